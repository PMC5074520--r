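# Parsing of annotated transcripts, candidate start-site enumeration and
# true/false labeling against a reported (ribosome-profiling-derived)
# start-site table.
#
# Position convention (Kozak style): the first nt of the annotated CDS is
# position +1, the nt immediately upstream is -1; there is no position 0.
# A candidate's position is the offset of its codon's first nucleotide, so
# all 5' UTR candidates have position <= -3.

#' Construct an annotated transcript
#'
#' @param id Transcript identifier.
#' @param sequence mRNA sequence (RNA or DNA; T is converted to U).
#' @param cds_start 1-based index of the first nucleotide of the annotated
#'   CDS; the 5' UTR is the prefix of length `cds_start - 1`.
#' @return Object of class `tis_transcript` with fields `id`, `sequence`,
#'   `cds_start`, `utr5` and `cds`.
#' @export
transcript <- function(id, sequence, cds_start) {
  sequence <- as_rna(sequence)
  cds_start <- as.integer(cds_start)
  if (is.na(cds_start) || cds_start < 1L || cds_start > nchar(sequence)) {
    stop("transcript '", id, "': cds_start (", cds_start,
         ") out of range for sequence of length ", nchar(sequence))
  }
  structure(
    list(
      id = as.character(id),
      sequence = sequence,
      cds_start = cds_start,
      utr5 = substr(sequence, 1L, cds_start - 1L),
      cds = substr(sequence, cds_start, nchar(sequence))
    ),
    class = "tis_transcript"
  )
}

#' @export
print.tis_transcript <- function(x, ...) {
  cat("<tis_transcript> ", x$id, ": ", nchar(x$sequence), " nt (5'UTR ",
      nchar(x$utr5), " nt, CDS ", nchar(x$cds), " nt)\n", sep = "")
  invisible(x)
}

# Transcript index of a Kozak-style position relative to a codon whose first
# nt sits at transcript index i0 (+1 = i0; no position 0).
kozak_index <- function(i0, q) ifelse(q >= 1L, i0 + q - 1L, i0 + q)

#' Read annotated transcripts from FASTA
#'
#' The CDS start is taken from a `cds_start=<int>` tag in the FASTA header
#' or from a sidecar annotation table (`transcript_id<TAB>cds_start`,
#' 1-based). The sidecar wins when both are present. Records without any
#' CDS-start annotation are skipped with a warning.
#'
#' @param fasta_path Path to a FASTA file (plain or gzip).
#' @param annotation Optional path to the sidecar TSV, or a data frame with
#'   columns `transcript_id` and `cds_start`.
#' @return List of [transcript()] objects, named by id.
#' @export
parse_transcripts <- function(fasta_path, annotation = NULL) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e))
  )
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  tag <- suppressWarnings(
    as.integer(ifelse(grepl("cds_start=", headers),
                      sub(".*cds_start=([0-9]+).*", "\\1", headers), NA))
  )
  side <- rep(NA_integer_, length(ids))
  if (!is.null(annotation)) {
    ann <- if (is.data.frame(annotation)) annotation else {
      utils::read.delim(annotation, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
    stopifnot(all(c("transcript_id", "cds_start") %in% names(ann)))
    side <- as.integer(ann$cds_start[match(ids, ann$transcript_id)])
  }
  cds_start <- ifelse(is.na(side), tag, side)
  skip <- is.na(cds_start)
  if (any(skip)) {
    warning(sum(skip), " record(s) without cds_start skipped: ",
            paste(utils::head(ids[skip], 5), collapse = ", "))
  }
  out <- Map(transcript, ids[!skip], as.character(seqs)[!skip],
             cds_start[!skip])
  names(out) <- ids[!skip]
  out
}

#' Enumerate candidate start sites in a 5' UTR
#'
#' Scans every offset of the 5' UTR and emits a candidate for each triplet
#' that (i) belongs to the ten-codon AUG/near-cognate alphabet, (ii) has a
#' downstream in-frame stop codon somewhere in the transcript, and (iii) has
#' at least `window` nt of transcript sequence on both sides of the codon.
#' Labels are initialised to `"EXCLUDED"` (unlabeled).
#'
#' @param tx A [transcript()].
#' @param window Required flank length in nt (default 99).
#' @param stop_before_cds_end If `TRUE`, the downstream in-frame stop must
#'   begin before the last codon of the transcript's annotated CDS; default
#'   `FALSE` (the whole transcript is searched).
#' @return Data frame with columns `transcript_id`, `position`, `codon`,
#'   `frame` ("in_frame"/"out_of_frame"), `orf_length_nt`, `label`, sorted
#'   by position. Zero rows if no candidate qualifies.
#' @export
enumerate_candidates <- function(tx, window = 99, stop_before_cds_end = FALSE) {
  empty <- data.frame(
    transcript_id = character(), position = integer(), codon = character(),
    frame = character(), orf_length_nt = integer(), label = character(),
    stringsAsFactors = FALSE
  )
  n <- nchar(tx$sequence)
  utr_len <- tx$cds_start - 1L
  if (utr_len < 3L) return(empty)
  i <- seq_len(utr_len - 2L)                    # codon fully inside the UTR
  i <- i[i >= window + 1L & i + 2L + window <= n]
  if (!length(i)) return(empty)
  cod <- substring(tx$sequence, i, i + 2L)
  keep <- cod %in% start_codon_alphabet()
  i <- i[keep]; cod <- cod[keep]
  if (!length(i)) return(empty)
  orf <- vapply(i, function(ii) orf_length_at(tx$sequence, ii), integer(1))
  if (stop_before_cds_end) {
    # stop codon must begin within the annotated transcript CDS span
    last_ok <- n - 2L
    drop <- orf > 0L & (i + orf - 3L) > last_ok
    orf[drop] <- 0L
  }
  keep <- orf > 0L
  i <- i[keep]; cod <- cod[keep]; orf <- orf[keep]
  if (!length(i)) return(empty)
  pos <- i - tx$cds_start                       # negative, no position 0
  data.frame(
    transcript_id = tx$id,
    position = as.integer(pos),
    codon = cod,
    frame = ifelse(pos %% 3L == 0L, "in_frame", "out_of_frame"),
    orf_length_nt = as.integer(orf),
    label = "EXCLUDED",
    stringsAsFactors = FALSE
  )
}

# ORF length in nt from the codon at index i through the first downstream
# in-frame stop, inclusive; 0L if no stop exists.
orf_length_at <- function(seq, i) {
  n <- nchar(seq)
  starts <- seq.int(i + 3L, by = 3L, length.out = max(0L, (n - 2L - i) %/% 3L))
  if (!length(starts)) return(0L)
  cods <- substring(seq, starts, starts + 2L)
  hit <- which(cods %in% STOP_CODONS)
  if (!length(hit)) return(0L)
  as.integer(starts[hit[1]] + 2L - i + 1L)
}

#' Read a reported start-site table
#'
#' Tab-separated columns `transcript_id`, `position`, `codon`, as distributed
#' with ribosome-profiling start-site supplements: positions are negative
#' integers relative to the annotated start (+1), codons from the ten-codon
#' alphabet.
#'
#' @param path TSV path, or a data frame with those columns.
#' @return Validated data frame.
#' @export
read_reported_tis <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("transcript_id", "position", "codon") %in% names(tab)))
  tab$position <- as.integer(tab$position)
  if (any(tab$position >= 0L)) stop("reported positions must be negative")
  tab$codon <- as_rna(tab$codon)
  bad <- !tab$codon %in% start_codon_alphabet()
  if (any(bad)) stop("reported codons outside the start-codon alphabet: ",
                     paste(unique(tab$codon[bad]), collapse = ", "))
  tab
}

#' Label candidates as true or false start sites
#'
#' A candidate is `TRUE_START` when its (transcript, position) appears in the
#' reported table (the codon is cross-checked; a mismatch raises a warning).
#' Unreported candidates become `FALSE_START` when they lie at least
#' `window` nt downstream of the transcript 5' end (guaranteed by
#' enumeration) and strictly upstream of the transcript's most downstream
#' reported true start; everything else, including every candidate of a
#' transcript with no reported start, stays `EXCLUDED`.
#'
#' @param candidates Data frame from [enumerate_candidates()] (one or more
#'   transcripts, row-bound).
#' @param reported Reported start-site table ([read_reported_tis()]).
#' @return `candidates` with the `label` column filled in.
#' @export
label_candidates <- function(candidates, reported) {
  reported <- read_reported_tis(reported)
  if (!nrow(candidates)) return(candidates)
  key <- paste(candidates$transcript_id, candidates$position)
  rkey <- paste(reported$transcript_id, reported$position)
  hit <- match(key, rkey)
  is_true <- !is.na(hit)
  mism <- is_true & candidates$codon != reported$codon[hit]
  if (any(mism)) {
    warning("codon mismatch between enumeration and reported table for: ",
            paste(key[mism], collapse = "; "))
  }
  orphan <- !(rkey %in% key)
  if (any(orphan)) {
    message("reported start(s) with no enumerated candidate (no full flanks ",
            "or no in-frame stop): ", paste(rkey[orphan], collapse = "; "))
  }
  anchor <- tapply(reported$position, reported$transcript_id, max)
  anch <- anchor[candidates$transcript_id]
  lab <- rep("EXCLUDED", nrow(candidates))
  lab[is_true] <- "TRUE_START"
  lab[!is_true & !is.na(anch) & candidates$position < anch] <- "FALSE_START"
  candidates$label <- lab
  candidates[order(candidates$transcript_id, candidates$position), ,
             drop = FALSE]
}

#' Write a candidate table
#'
#' @param candidates Candidate data frame.
#' @param path Output path; format by extension (`.csv` or `.tsv`).
#' @export
write_candidates <- function(candidates, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(candidates, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
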