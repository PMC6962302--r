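#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a deterministic stage sub-seed from a master seed
#'
#' Every randomized stage of the pipeline receives its own sub-seed so that
#' stages can be re-run in isolation yet the whole run stays reproducible
#' from one master seed. Sub-seeds stay below 2^31 - 1.
#'
#' @param master Master integer seed.
#' @param stage Stage name (character) or index.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master))
  key <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage) * 7919
  }
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m)
  s <- (s * 48271 + key * 16807 + 12345) %% m
  as.integer(max(1, s))
}

#' Construct an omics matrix
#'
#' A features x samples numeric matrix carrying an omics-layer tag. This is
#' the container consumed by the differential screen and the models.
#'
#' @param values Numeric matrix, features in rows, samples in columns; must
#'   have row and column names.
#' @param layer One of `"methylation"` (beta values in `[0,1]`) or
#'   `"expression"` (positive normalized intensities).
#' @return A numeric matrix of class `omics_matrix` with a `layer` attribute.
#' @export
omics_matrix <- function(values, layer = c("methylation", "expression")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames")
  }
  if (layer == "methylation") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("methylation beta values must lie in [0, 1]")
    }
  }
  if (layer == "expression" && any(values <= 0, na.rm = TRUE)) {
    stop("expression values must be positive")
  }
  structure(values, layer = layer, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "omics_matrix [%s]: %d features x %d samples\n",
    attr(x, "layer"), nrow(x), ncol(x)
  ))
  invisible(x)
}

omics_layer <- function(x) attr(x, "layer") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a
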