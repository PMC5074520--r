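# Position frequency / weight matrices over the start-site context window.
#
# The context window spans 15 nt upstream of the codon, the codon itself and
# 10 nt downstream (28 nt; Kozak positions -15..-1, +1..+3, +4..+13). The
# alternative "literal" window -15..+10 (25 nt) is available via
# `window_mode = "literal"` wherever a context is extracted.

CONTEXT_UP <- 15L

context_down <- function(window_mode = c("extended", "literal")) {
  if (match.arg(window_mode) == "extended") 10L else 7L
}

# Kozak positions of the context window, in order (codon included).
context_positions <- function(window_mode = "extended") {
  c(-CONTEXT_UP:-1, 1:3, 4:(3 + context_down(window_mode)))
}

# Context string for codon at transcript index i0 (NA if out of bounds).
context_at <- function(seq, i0, window_mode = "extended") {
  a <- i0 - CONTEXT_UP
  b <- i0 + 2L + context_down(window_mode)
  if (a < 1L || b > nchar(seq)) return(NA_character_)
  substr(seq, a, b)
}

#' Build the three context position-weight matrices
#'
#' A position-frequency matrix (PFM) is counted per class (true / false
#' start contexts), a pseudocount added per cell, and each entry divided by
#' the column total. The positive and negative PWMs are the natural log of
#' the PFM over the background nucleotide frequency, the ratio PWM the log
#' of the positive over the negative PFM (elementwise, so pwm_ratio =
#' pwm_pos - pwm_neg).
#'
#' @param true_contexts,false_contexts Character vectors of equal-length
#'   context strings (at least one per class).
#' @param bg Background frequency for A, C, G, U: either a named numeric
#'   vector summing to 1, or a character vector / list of training-set
#'   5' UTR sequences whose pooled nucleotide frequency is used.
#' @param pseudocount Count added to every PFM cell (default 0.5).
#' @return Object of class `tis_pwm` with fields `pfm_pos`, `pfm_neg`,
#'   `pwm_pos`, `pwm_neg`, `pwm_ratio` (4 x width matrices), `bg`, `width`.
#' @export
build_pwm_model <- function(true_contexts, false_contexts, bg,
                            pseudocount = 0.5) {
  stopifnot(length(true_contexts) >= 1, length(false_contexts) >= 1)
  w <- unique(nchar(c(true_contexts, false_contexts)))
  if (length(w) != 1L) stop("contexts must all have identical length")
  if (is.character(bg) || is.list(bg)) {
    cnt <- Reduce(`+`, lapply(unlist(bg), nt_counts))
    bg <- cnt / sum(cnt)
  }
  bg <- bg[NT]
  if (any(is.na(bg)) || abs(sum(bg) - 1) > 1e-6) {
    stop("background must provide frequencies for A, C, G, U summing to 1")
  }
  if (any(bg == 0)) stop("zero background frequency; cannot log-scale")
  pfm_pos <- count_pfm(true_contexts, w, pseudocount)
  pfm_neg <- count_pfm(false_contexts, w, pseudocount)
  structure(
    list(
      pfm_pos = pfm_pos, pfm_neg = pfm_neg, bg = bg,
      pwm_pos = log(pfm_pos / bg), pwm_neg = log(pfm_neg / bg),
      pwm_ratio = log(pfm_pos / pfm_neg),
      width = w, pseudocount = pseudocount
    ),
    class = "tis_pwm"
  )
}

count_pfm <- function(contexts, w, pseudocount) {
  m <- matrix(pseudocount, nrow = 4, ncol = w, dimnames = list(NT, NULL))
  ch <- matrix(unlist(strsplit(contexts, "", fixed = TRUE)),
               nrow = w)                      # positions x sequences
  for (i in seq_len(w)) {
    tab <- tabulate(match(ch[i, ], NT), nbins = 4L)
    m[, i] <- m[, i] + tab
  }
  sweep(m, 2, colSums(m), "/")
}

#' Score a context against a position weight matrix
#'
#' Sum over all window positions of the matrix entry for the nucleotide
#' observed at that position. For the positive PWM, a score above zero
#' marks a context more typical of true than of false starts.
#'
#' @param context Context string(s) of the matrix width.
#' @param matrix A 4 x width numeric matrix with rows A, C, G, U (e.g.
#'   `model$pwm_pos` from [build_pwm_model()]).
#' @return Numeric vector of scores.
#' @export
pwm_score <- function(context, matrix) {
  w <- ncol(matrix)
  bad <- nchar(context) != w
  if (any(bad, na.rm = TRUE)) {
    stop("context length ", nchar(context[which(bad)[1]]),
         " does not match matrix width ", w)
  }
  out <- rep(NA_real_, length(context))
  ok <- !is.na(context)
  if (any(ok)) {
    ch <- matrix(unlist(strsplit(context[ok], "", fixed = TRUE)), nrow = w)
    idx <- match(ch, rownames(matrix))   # column j of `ch` is context j
    sc <- matrix(matrix[cbind(as.vector(idx),
                              rep(seq_len(w), times = sum(ok)))], nrow = w)
    out[ok] <- colSums(sc)
  }
  out
}
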