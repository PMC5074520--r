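# Human-ortholog conservation features. The ortholog transcript is supplied
# explicitly (no homology search); alignment uses global (Needleman-Wunsch)
# pairwise alignment: BLOSUM62 with gap open 11 / extend 1 for proteins,
# match +2 / mismatch -3 with gap open 5 / extend 2 for nucleotides.
# Protein alignments of all three reading frames of 5'UTR+CDS are computed,
# kept in-line with stop codons rendered as "*", and back-translated to
# locate the ortholog codon aligned to a candidate start.

# Missing-ortholog sentinel.
missing_pair <- function(primary) {
  structure(list(primary = primary, ortholog = NULL, has_ortholog = FALSE),
            class = "tis_ortholog_pair")
}

#' Align a transcript with its ortholog
#'
#' For each reading frame of the primary transcript, the concatenated
#' 5'UTR+CDS is translated (stops kept in-line as "*") and globally aligned
#' against all three ortholog frames; by default the best-scoring ortholog
#' frame is retained per primary frame (`frame_pairing = "best"`), or frames
#' can be paired index-to-index (`"matched"`). A separate global nucleotide
#' alignment of the two 5' UTRs is produced for UTR-level conservation.
#'
#' @param primary,ortholog [transcript()] objects; `ortholog` may be `NULL`,
#'   in which case a missing-pair sentinel is returned and downstream
#'   conservation features take their documented defaults (all zero).
#' @param frame_pairing `"best"` (default) or `"matched"`.
#' @return Object of class `tis_ortholog_pair`.
#' @export
align_orthologs <- function(primary, ortholog, frame_pairing = c("best", "matched")) {
  frame_pairing <- match.arg(frame_pairing)
  if (is.null(ortholog)) return(missing_pair(primary))
  p_prot <- lapply(0:2, function(f) translate_rna(primary$sequence, f))
  o_prot <- lapply(0:2, function(f) translate_rna(ortholog$sequence, f))
  sub <- get_blosum62()
  frames <- vector("list", 3)
  for (f in 0:2) {
    if (!nzchar(p_prot[[f + 1]])) next
    cand <- if (frame_pairing == "matched") f else 0:2
    best <- NULL
    for (g in cand) {
      if (!nzchar(o_prot[[g + 1]])) next
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(p_prot[[f + 1]]),
        Biostrings::AAString(o_prot[[g + 1]]),
        substitutionMatrix = sub, gapOpening = 11, gapExtension = 1,
        type = "global"
      )
      if (is.null(best) || Biostrings::score(al) > best$score) {
        best <- list(
          score = Biostrings::score(al),
          ortholog_frame = g,
          pattern = as.character(Biostrings::alignedPattern(al)),
          subject = as.character(Biostrings::alignedSubject(al))
        )
      }
    }
    frames[[f + 1]] <- best
  }
  nt_al <- NULL
  if (nchar(primary$utr5) > 0 && nchar(ortholog$utr5) > 0) {
    ntsub <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE
    )
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(chartr("U", "T", primary$utr5)),
      Biostrings::DNAString(chartr("U", "T", ortholog$utr5)),
      substitutionMatrix = ntsub, gapOpening = 5, gapExtension = 2,
      type = "global"
    )
    nt_al <- list(
      pattern = chartr("T", "U", as.character(Biostrings::alignedPattern(al))),
      subject = chartr("T", "U", as.character(Biostrings::alignedSubject(al)))
    )
  }
  structure(
    list(primary = primary, ortholog = ortholog, has_ortholog = TRUE,
         frames = frames, nt_alignment = nt_al),
    class = "tis_ortholog_pair"
  )
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Start-site conservation
#'
#' A candidate start is codon-conserved when the ortholog codon aligned to
#' it (through the back-translated protein alignment of the candidate's
#' reading frame) is identical, and amino-acid-conserved when both codons
#' translate to the same residue under the standard genetic code (the
#' near-cognate codon is translated literally, e.g. CUG -> Leu). Gap or
#' unalignable positions, and missing orthologs, yield (0, 0).
#'
#' @param candidate One row of a candidate data frame.
#' @param pair A `tis_ortholog_pair` from [align_orthologs()].
#' @return Named numeric vector `c(codon_conserved=, aa_conserved=)`.
#' @export
start_conservation <- function(candidate, pair) {
  none <- c(codon_conserved = 0, aa_conserved = 0)
  if (!isTRUE(pair$has_ortholog)) return(none)
  i0 <- pair$primary$cds_start + candidate$position   # codon first nt index
  f <- (i0 - 1L) %% 3L
  al <- pair$frames[[f + 1L]]
  if (is.null(al)) return(none)
  k <- (i0 - 1L - f) %/% 3L + 1L                       # codon rank in frame f
  pat <- strsplit(al$pattern, "", fixed = TRUE)[[1]]
  subj <- strsplit(al$subject, "", fixed = TRUE)[[1]]
  col <- which(cumsum(pat != "-") == k & pat != "-")[1]
  if (is.na(col) || subj[col] == "-") return(none)
  m <- sum(subj[seq_len(col)] != "-")                  # ortholog codon rank
  g <- al$ortholog_frame
  o_start <- g + 3L * (m - 1L) + 1L
  orth_codon <- substr(pair$ortholog$sequence, o_start, o_start + 2L)
  prim_codon <- substr(pair$primary$sequence, i0, i0 + 2L)
  ct <- codon_table()
  c(
    codon_conserved = as.numeric(orth_codon == prim_codon),
    aa_conserved = as.numeric(!is.na(ct[orth_codon]) &&
                                ct[orth_codon] == ct[prim_codon])
  )
}

#' 5' UTR sequence conservation
#'
#' Fraction of the primary 5' UTR whose aligned ortholog nucleotide is
#' identical: matching alignment columns divided by the primary 5' UTR
#' length; gap columns count only in the denominator.
#'
#' @param pair A `tis_ortholog_pair`.
#' @return Fraction in [0, 1]; 0 when the ortholog is missing.
#' @export
utr_conservation <- function(pair) {
  if (!isTRUE(pair$has_ortholog) || is.null(pair$nt_alignment)) return(0)
  if (nchar(pair$primary$utr5) == 0L) stop("empty 5' UTR")
  pat <- strsplit(pair$nt_alignment$pattern, "", fixed = TRUE)[[1]]
  subj <- strsplit(pair$nt_alignment$subject, "", fixed = TRUE)[[1]]
  matches <- sum(pat == subj & pat != "-")
  matches / nchar(pair$primary$utr5)
}

#' Read an ortholog pairing table
#'
#' @param path TSV with columns `primary_id`, `ortholog_id`, or a data frame.
#' @return Data frame with those columns.
#' @export
read_pairing <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("primary_id", "ortholog_id") %in% names(tab)))
  tab
}

# Build one tis_ortholog_pair per primary transcript (missing sentinel when
# no ortholog is paired). `pairing` maps primary ids to ortholog ids.
build_pairs <- function(transcripts, orthologs = NULL, pairing = NULL, ...) {
  out <- lapply(transcripts, function(tx) {
    oid <- if (!is.null(pairing)) {
      pairing$ortholog_id[match(tx$id, pairing$primary_id)]
    } else NA_character_
    orth <- if (!is.na(oid) && !is.null(orthologs[[oid]])) orthologs[[oid]]
    align_orthologs(tx, orth, ...)
  })
  names(out) <- vapply(transcripts, `[[`, "", "id")
  out
}
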