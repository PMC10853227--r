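#' @importFrom rlang %||% abort warn
#' @importFrom stats sd quantile median cor rnorm runif rbinom predict coef
#' @importFrom stats hclust cutree as.dist dist optim uniroot integrate dnorm
#' @importFrom stats smooth.spline p.adjust wilcox.test qnorm setNames var
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    genv <- globalenv()
    if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      old <- get(".Random.seed", envir = genv)
      on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p)) %% 2147483582
  as.integer(s) + 1L
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) abort(msg)

# Strip the id column off a feature table, keep numeric feature matrix.
feature_matrix <- function(df, id_col = "patient_id") {
  df <- as.data.frame(df)
  feats <- setdiff(names(df), id_col)
  bad <- feats[!vapply(df[feats], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric feature columns: ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(df[feats])
  rownames(m) <- if (id_col %in% names(df)) as.character(df[[id_col]]) else NULL
  m
}

is_conventional <- function(nms) startsWith(nms, "conv_")
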