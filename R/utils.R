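# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stopf("`%s` = %g outside %s%g, %g%s", name, x,
          if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stopf("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# Deterministic child seeds for pipeline sub-stages; kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

# TSV writers used for every exported table: plain, header, no quoting.
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

covariate_names <- function() c("sex", "age", "area", "bmi")

# Extract the covariate design matrix (no intercept) from a phenotype frame.
covariate_matrix <- function(pheno) {
  need <- covariate_names()
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stopf("phenotype frame lacks covariate column(s): %s",
          paste(miss, collapse = ", "))
  m <- as.matrix(pheno[, need])
  if (anyNA(m)) stopf("covariates contain missing values")
  storage.mode(m) <- "double"
  m
}
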