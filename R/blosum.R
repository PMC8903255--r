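# BLOSUM62 handling.  The raw integer matrix comes from Biostrings; it is
# cached at first use.  Raw scores break ties between equal-length seeds;
# the scaled form defines the M-seq score.

.pm_env <- new.env(parent = emptyenv())

blosum62_raw <- function() {
  if (is.null(.pm_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pm_env$b62 <- e$BLOSUM62
  }
  .pm_env$b62
}

#' Scaled BLOSUM-62 substitution score
#'
#' Substitution values rescaled to `[0, 1]`:
#' `s(a, b) = max(0, B62(a, b)) / min(B62(a, a), B62(b, b))`, so every
#' standard residue scores 1 against itself and negative substitutions
#' clamp to 0.  The placeholder `"X"` (non-standard residue without a
#' parent amino acid) scores 0 against everything, i.e. worst case.
#'
#' @param a,b one-letter amino-acid codes (vectorised; `"X"` allowed).
#' @return numeric in `[0, 1]`, recycled to the common length.
#' @export
scaled_blosum <- function(a, b) {
  ok <- c(AA20, "X")
  if (!all(a %in% ok) || !all(b %in% ok))
    stop("unknown amino-acid code(s): ",
         paste(unique(setdiff(c(a, b), ok)), collapse = ", "))
  nn <- max(length(a), length(b))
  a <- rep_len(a, nn); b <- rep_len(b, nn)
  B <- blosum62_raw()
  out <- numeric(nn)
  std <- a != "X" & b != "X"
  if (any(std)) {
    raw <- B[cbind(a[std], b[std])]
    self <- pmin(B[cbind(a[std], a[std])], B[cbind(b[std], b[std])])
    out[std] <- pmin(1, pmax(0, raw) / self)
  }
  out
}

# Raw BLOSUM62 lookup used for seed tie-breaking; X scores through the
# published X row/column.
raw_blosum <- function(a, b) {
  B <- blosum62_raw()
  B[cbind(a, b)]
}
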