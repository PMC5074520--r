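# Secondary-structure stability proxy and GC content for fixed windows
# around a candidate start site.
#
# The built-in folding engine is a Nussinov-style dynamic program over
# non-crossing base pairings with pair weights GC = -3, AU = -2, GU = -1
# kcal/mol and a minimum hairpin loop of 3 unpaired nt. It is a simplified
# stability proxy, NOT a nearest-neighbour (Turner) energy model; any
# callable with the same signature can be plugged in instead (e.g. an
# adapter around an external Turner-model folder).

#' Built-in folding-stability proxy
#'
#' @param seqs Character vector of RNA strings.
#' @param minloop Minimum number of unpaired nt enclosed by a pair.
#' @return Numeric vector of minimum energies (kcal/mol, <= 0).
#' @export
mfe_nussinov <- function(seqs, minloop = 3L) {
  if (!length(seqs)) return(numeric(0))
  .nussinov_mfe(as.character(seqs), as.integer(minloop))
}

#' RNAfold adapter (optional plug-in)
#'
#' Thin wrapper calling an external `RNAfold` executable when one is on the
#' PATH, for users who want nearest-neighbour (Turner model) energies
#' instead of the built-in proxy. Never used by default.
#'
#' @param seqs Character vector of RNA strings.
#' @return Numeric vector of minimum free energies (kcal/mol).
#' @export
mfe_rnafold <- function(seqs) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) stop("RNAfold executable not found on PATH")
  out <- system2(exe, args = c("--noPS"), input = paste(seqs, collapse = "\n"),
                 stdout = TRUE)
  en <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", en))
}

# Memoising wrapper: results keyed by window sequence, so the incremental
# and full-recompute mutagenesis modes agree bit-for-bit.
mfe_cached <- function(engine, cache = new.env(parent = emptyenv())) {
  function(seqs) {
    seqs <- as.character(seqs)
    vapply(seqs, function(s) {
      v <- cache[[s]]
      if (is.null(v)) {
        v <- engine(s)
        cache[[s]] <- v
      }
      v
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' GC content of a string
#'
#' @param x RNA string(s).
#' @return Fraction of G+C, 0 for empty strings.
#' @export
gc_content <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n > 0, gc / n, 0)
}

# The four energy/GC windows, in Kozak coordinates relative to the candidate
# codon's first nt (+1): two 60-nt windows starting at +14 and +20, a
# -10..+50 window and a -50..+50 window.
FOLD_WINDOWS <- list(
  p14    = c(14L, 73L),
  p20    = c(20L, 79L),
  m10p50 = c(-10L, 50L),
  m50p50 = c(-50L, 50L)
)

# Extract a Kozak-coordinate window around codon index i0, truncating at the
# transcript bounds. Returns the window string plus a truncation flag.
window_seq <- function(seq, i0, qfrom, qto) {
  a <- kozak_index(i0, qfrom)
  b <- kozak_index(i0, qto)
  ta <- max(1L, a)
  tb <- min(nchar(seq), b)
  list(seq = if (ta <= tb) substr(seq, ta, tb) else "",
       truncated = (ta != a) || (tb != b))
}

#' Folding-energy and GC features for one candidate
#'
#' Computes the stability proxy and GC content for the four standard windows
#' (+14..+73, +20..+79, -10..+50, -50..+50 in Kozak coordinates). Windows
#' are truncated at transcript bounds; an empty window yields 0 with a
#' truncation flag.
#'
#' @param tx A [transcript()].
#' @param candidate One candidate row (needs `position`).
#' @param mfe_engine Folding engine (default [mfe_nussinov()]).
#' @return List with numeric vectors `mfe` and `gc` (named p14, p20, m10p50,
#'   m50p50) and logical `truncated`.
#' @export
window_features <- function(tx, candidate, mfe_engine = mfe_nussinov) {
  i0 <- tx$cds_start + candidate$position
  ws <- lapply(FOLD_WINDOWS, function(w) window_seq(tx$sequence, i0, w[1], w[2]))
  seqs <- vapply(ws, `[[`, "", "seq")
  mfe <- ifelse(nzchar(seqs), mfe_engine(seqs), 0)
  gc <- gc_content(seqs)
  names(mfe) <- names(gc) <- names(FOLD_WINDOWS)
  list(mfe = mfe, gc = gc,
       truncated = vapply(ws, `[[`, logical(1), "truncated"))
}
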