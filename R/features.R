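# Per-candidate feature computation: Kozak class, flanking-context
# translational efficiency, 5' UTR composition, the 1,229-slot k-mer search
# and the assembly of the full 1,252-slot feature vector / matrix.

#' Kozak context class
#'
#' Discretizes the -3/+4 context: strong (A or G at -3 and G at +4) -> 4,
#' intermediate (A or G at -3, no G at +4) -> 3, weak (no A/G at -3, G at
#' +4) -> 2, no Kozak context -> 1.
#'
#' @param minus3,plus4 Single nucleotides at Kozak positions -3 and +4.
#' @return Integer in 1..4 (vectorized).
#' @export
kozak_class <- function(minus3, plus4) {
  purine <- minus3 %in% c("A", "G")
  g4 <- plus4 == "G"
  ifelse(purine & g4, 4L, ifelse(purine, 3L, ifelse(g4, 2L, 1L)))
}

#' Load a flanking-context translational-efficiency table
#'
#' Tab-separated columns `context` (11-nt string: positions -6..+5 around an
#' AUG) and `efficiency`. The table is indexed into a hash for O(1) lookup.
#'
#' @param path TSV path or data frame with those columns.
#' @return Object of class `tis_efficiency`.
#' @export
read_efficiency_table <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("context", "efficiency") %in% names(tab)))
  env <- new.env(parent = emptyenv(), size = nrow(tab))
  for (i in seq_len(nrow(tab))) env[[tab$context[i]]] <- tab$efficiency[i]
  structure(list(env = env, mean = mean(tab$efficiency), n = nrow(tab)),
            class = "tis_efficiency")
}

#' Flanking-context translational efficiency of a candidate
#'
#' Looks up the candidate's 11-nt context (-6..+5) with the candidate codon
#' replaced by AUG, under the assumption that near-cognate starts behave
#' like AUG starts with the same flanks. A context absent from the table
#' falls back to the table mean with a warning.
#'
#' @param tx A [transcript()].
#' @param candidate Candidate row (needs `position`).
#' @param efficiency A `tis_efficiency` from [read_efficiency_table()].
#' @return Efficiency value (numeric scalar).
#' @export
context_efficiency <- function(tx, candidate, efficiency) {
  i0 <- tx$cds_start + candidate$position
  ctx <- substr(tx$sequence, i0 - 6L, i0 + 4L)
  if (nchar(ctx) < 11L) {
    warning("incomplete -6..+5 context; using table mean")
    return(efficiency$mean)
  }
  substr(ctx, 7L, 9L) <- "AUG"
  v <- efficiency$env[[ctx]]
  if (is.null(v)) {
    warning("context ", ctx, " absent from efficiency table; using table mean")
    return(efficiency$mean)
  }
  v
}

#' 5' UTR length and nucleotide composition
#'
#' @param tx A [transcript()].
#' @return Named vector: `length`, `frac_A`, `frac_C`, `frac_G`, `frac_U`
#'   (fractions sum to 1).
#' @export
utr_stats <- function(tx) {
  n <- nchar(tx$utr5)
  if (n == 0L) stop("empty 5' UTR")
  cnt <- nt_counts(tx$utr5)
  c(length = n, frac_A = cnt[["A"]] / n, frac_C = cnt[["C"]] / n,
    frac_G = cnt[["G"]] / n, frac_U = cnt[["U"]] / n)
}

# Overlapping triplet counts of a string as a 64-slot vector (codon order of
# all_codons()); frame-locked counting uses stride 3 from the string start.
triplet_counts <- function(x, stride = 1L) {
  n <- nchar(x)
  out <- integer(64L)
  if (n >= 3L) {
    starts <- seq.int(1L, n - 2L, by = stride)
    cods <- substring(x, starts, starts + 2L)
    out <- tabulate(match(cods, all_codons()), nbins = 64L)
  }
  names(out) <- all_codons()
  out
}

#' k-mer features of a candidate
#'
#' Emits the 1,229 k-mer slots for a candidate with full flanks:
#' 792 position-specific nucleotide indicators over the upstream and
#' downstream windows (codon excluded), 320 overlapping triplet counts in
#' five regions (complete = upstream + codon + downstream, upstream flank,
#' downstream flank, and frame-locked in-frame upstream / downstream with
#' stride 3), 100 amino-acid counts and 5 stop-codon counts derived from the
#' triplet counts through the standard genetic code, and 12 single-nucleotide
#' counts over the complete / upstream / downstream regions.
#'
#' @param tx A [transcript()].
#' @param candidate Candidate row (needs `position`).
#' @param window Flank length (default 99; must be a multiple of 3 for the
#'   frame-locked regions to tile the flank).
#' @return Named numeric vector of length `8 * window + 437` (1,229 for the
#'   default window).
#' @export
kmer_features <- function(tx, candidate, window = 99L) {
  i0 <- tx$cds_start + candidate$position
  if (i0 - window < 1L || i0 + 2L + window > nchar(tx$sequence)) {
    stop("candidate at position ", candidate$position,
         " lacks the full ", window, "-nt flanks")
  }
  up <- substr(tx$sequence, i0 - window, i0 - 1L)
  codon <- substr(tx$sequence, i0, i0 + 2L)
  down <- substr(tx$sequence, i0 + 3L, i0 + 2L + window)
  complete <- paste0(up, codon, down)

  reg <- feature_registry(window)
  # position-specific single-nt indicators, codon excluded
  ch <- strsplit(paste0(up, down), "", fixed = TRUE)[[1]]
  ind <- matrix(0L, nrow = 2L * window, ncol = 4L)
  ind[cbind(seq_along(ch), match(ch, NT))] <- 1L
  pos_feat <- as.vector(t(ind))
  names(pos_feat) <- reg$kmer_pos

  cod_counts <- list(
    all = triplet_counts(complete),
    up = triplet_counts(up),
    down = triplet_counts(down),
    inframe_up = triplet_counts(up, stride = 3L),
    inframe_down = triplet_counts(down, stride = 3L)
  )
  ct <- codon_table()
  aa_of <- ct[all_codons()]
  cod_feat <- unlist(lapply(cod_counts, unname), use.names = FALSE)
  names(cod_feat) <- reg$kmer_codon
  aa_feat <- unlist(lapply(cod_counts, function(cc) {
    vapply(names(AA3), function(a) sum(cc[aa_of == a]), numeric(1))
  }), use.names = FALSE)
  names(aa_feat) <- reg$kmer_aa
  stop_feat <- vapply(cod_counts, function(cc) sum(cc[STOP_CODONS]), numeric(1))
  names(stop_feat) <- reg$kmer_stop
  nt_feat <- c(nt_counts(complete), nt_counts(up), nt_counts(down))
  names(nt_feat) <- reg$kmer_nt

  c(pos_feat, cod_feat, aa_feat, stop_feat, nt_feat)
}

#' Extract the full feature vector of one candidate
#'
#' Assembles all 1,252 named feature slots: the three PWM scores (NA when
#' `pwm_model` is `NULL`, to be filled per training repetition), the 20
#' biologically motivated features and the 1,229 k-mer slots.
#'
#' @param tx A [transcript()].
#' @param candidate Candidate row.
#' @param pair `tis_ortholog_pair` for the transcript (or `NULL` = missing
#'   ortholog; conservation features default to 0).
#' @param efficiency `tis_efficiency` table.
#' @param pwm_model `tis_pwm` or `NULL` (scores deferred).
#' @param mfe_engine Folding engine (default [mfe_nussinov()]).
#' @param window k-mer flank length (default 99).
#' @return Named numeric vector with exactly the registry's slots, in order.
#' @export
extract_features <- function(tx, candidate, pair = NULL, efficiency,
                             pwm_model = NULL, mfe_engine = mfe_nussinov,
                             window = 99L) {
  reg <- feature_registry(window)
  i0 <- tx$cds_start + candidate$position
  ctx <- context_at(tx$sequence, i0)
  pwm <- c(pwm_pos_score = NA_real_, pwm_neg_score = NA_real_,
           pwm_ratio_score = NA_real_)
  if (!is.null(pwm_model)) {
    pwm <- c(pwm_pos_score = pwm_score(ctx, pwm_model$pwm_pos),
             pwm_neg_score = pwm_score(ctx, pwm_model$pwm_neg),
             pwm_ratio_score = pwm_score(ctx, pwm_model$pwm_ratio))
  }
  if (is.null(pair)) pair <- missing_pair(tx)
  cons <- start_conservation(candidate, pair)
  us <- utr_stats(tx)
  wf <- window_features(tx, candidate, mfe_engine = mfe_engine)
  orf_len <- candidate$orf_length_nt
  if (is.null(orf_len) || is.na(orf_len)) {
    orf_len <- orf_length_at(tx$sequence, i0)
  }
  bio <- c(
    utr_length = unname(us["length"]),
    utr_conservation = utr_conservation(pair),
    codon_conserved = unname(cons["codon_conserved"]),
    aa_conserved = unname(cons["aa_conserved"]),
    in_frame = as.numeric(candidate$position %% 3L == 0L),
    kozak_class = as.numeric(kozak_class(
      substr(tx$sequence, i0 - 3L, i0 - 3L),
      substr(tx$sequence, i0 + 3L, i0 + 3L)
    )),
    context_efficiency = context_efficiency(tx, candidate, efficiency),
    mfe_p14 = unname(wf$mfe["p14"]), mfe_p20 = unname(wf$mfe["p20"]),
    mfe_m10p50 = unname(wf$mfe["m10p50"]), mfe_m50p50 = unname(wf$mfe["m50p50"]),
    gc_p14 = unname(wf$gc["p14"]), gc_p20 = unname(wf$gc["p20"]),
    gc_m10p50 = unname(wf$gc["m10p50"]), gc_m50p50 = unname(wf$gc["m50p50"]),
    orf_length_nt = as.numeric(orf_len),
    utr_frac_A = unname(us["frac_A"]), utr_frac_C = unname(us["frac_C"]),
    utr_frac_G = unname(us["frac_G"]), utr_frac_U = unname(us["frac_U"])
  )
  out <- c(pwm, bio, kmer_features(tx, candidate, window))
  stopifnot(identical(names(out), reg$all))
  out
}

#' Assemble the feature matrix and modelling dataset for labeled candidates
#'
#' Extracts features for every `TRUE_START`/`FALSE_START` candidate and
#' bundles everything the training loop needs to rebuild PWMs per
#' repetition: the context strings and the per-transcript 5' UTR nucleotide
#' counts (training-set background frequencies are pooled from these).
#'
#' @param transcripts Named list of [transcript()] objects.
#' @param candidates Labeled candidate data frame.
#' @param pairs Named list of `tis_ortholog_pair` (may be `NULL`).
#' @param efficiency `tis_efficiency`.
#' @param mfe_engine Folding engine.
#' @param window k-mer flank length.
#' @return Object of class `tis_dataset`: `features` (n x 1,252 matrix),
#'   `labels` (0/1), `contexts`, `candidates`, `utr_counts`.
#' @export
build_dataset <- function(transcripts, candidates, pairs = NULL, efficiency,
                          mfe_engine = mfe_nussinov, window = 99L) {
  keep <- candidates$label %in% c("TRUE_START", "FALSE_START")
  cand <- candidates[keep, , drop = FALSE]
  if (!nrow(cand)) stop("no labeled candidates")
  rownames(cand) <- NULL
  reg <- feature_registry(window)
  X <- matrix(NA_real_, nrow = nrow(cand), ncol = length(reg$all),
              dimnames = list(NULL, reg$all))
  ctxs <- character(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    tx <- transcripts[[cand$transcript_id[r]]]
    pr <- if (!is.null(pairs)) pairs[[tx$id]] else NULL
    X[r, ] <- extract_features(tx, cand[r, ], pr, efficiency,
                               pwm_model = NULL, mfe_engine = mfe_engine,
                               window = window)
    ctxs[r] <- context_at(tx$sequence, tx$cds_start + cand$position[r])
  }
  ids <- unique(cand$transcript_id)
  utr_counts <- t(vapply(ids, function(id) nt_counts(transcripts[[id]]$utr5),
                         numeric(4)))
  rownames(utr_counts) <- ids
  structure(
    list(features = X, labels = as.numeric(cand$label == "TRUE_START"),
         contexts = ctxs, candidates = cand, utr_counts = utr_counts,
         window = window),
    class = "tis_dataset"
  )
}

#' @export
print.tis_dataset <- function(x, ...) {
  cat("<tis_dataset> ", nrow(x$features), " candidates (",
      sum(x$labels == 1), " true / ", sum(x$labels == 0), " false), ",
      ncol(x$features), " features\n", sep = "")
  invisible(x)
}

#' Export a feature matrix as CSV
#'
#' Writes candidate metadata columns followed by all feature slots, header
#' row included, suitable for downstream analyses.
#'
#' @param dataset A `tis_dataset`.
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(dataset, path) {
  df <- cbind(dataset$candidates, as.data.frame(dataset$features,
                                                check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
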