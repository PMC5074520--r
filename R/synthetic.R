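# Self-contained synthetic data: transcripts with planted true starts,
# ortholog copies, reported start-site tables emulating ribosome-profiling
# supplements, and a parametric stand-in flanking-context efficiency table.
# Decoy near-cognate candidates are not forced: false starts emerge from
# the random background composition, as they do in curated transcript sets.

#' Simulation parameters
#'
#' Defaults describe a realistic curated-transcript corpus: log-normal
#' 5' UTR lengths with mean 414 +/- 270 nt for transcripts carrying true
#' starts and 675 +/- 545 nt otherwise, start-codon usage dominated by AUG
#' (0.26), CUG (0.30) and GUG (0.13) with the remaining near-cognates
#' uniform, GC-rich 5' UTR background composition, and point-mutated
#' ortholog copies.
#'
#' @param n_transcripts Number of primary transcripts.
#' @param carrier_fraction Fraction of transcripts carrying true starts.
#' @param true_starts_rate Poisson rate; each carrier plants
#'   `1 + rpois(rate)` true starts.
#' @param utr_mean_true,utr_sd_true,utr_mean_false,utr_sd_false Log-normal
#'   moment targets (nt) for carrier / non-carrier 5' UTR lengths.
#' @param codon_probs Named start-codon usage for planted true starts.
#' @param kozak_strong Probability a planted start receives a strong Kozak
#'   context (A/G at -3 and G at +4).
#' @param context_motif_prob Probability a planted start receives the
#'   GCCACC consensus at -6..-1.
#' @param bg 5' UTR background nucleotide frequencies (A, C, G, U).
#' @param cds_codons_range CDS length range in codons (excluding the stop).
#' @param ortholog_mutation_rate Per-base substitution probability for the
#'   ortholog copy.
#' @param codon_conserved_prob Probability a planted start codon is restored
#'   (kept identical) in the ortholog.
#' @param min_utr,max_utr 5' UTR length clamp (nt); the lower bound leaves
#'   room for 99-nt flanks.
#' @param seed RNG seed.
#' @param strong_signal If `TRUE`, overrides the context parameters to make
#'   the two classes nearly separable (every true start gets a strong Kozak
#'   context and the consensus motif): `kozak_strong = 1`,
#'   `context_motif_prob = 1`.
#' @return List of class `tis_sim_params`.
#' @export
sim_params <- function(n_transcripts = 100, carrier_fraction = 0.8,
                       true_starts_rate = 0.3,
                       utr_mean_true = 414.41, utr_sd_true = 270.48,
                       utr_mean_false = 675.41, utr_sd_false = 545.35,
                       codon_probs = NULL, kozak_strong = 0.45,
                       context_motif_prob = 0.5,
                       bg = c(A = 0.21, C = 0.27, G = 0.30, U = 0.22),
                       cds_codons_range = c(120, 260),
                       ortholog_mutation_rate = 0.25,
                       codon_conserved_prob = 0.6,
                       min_utr = 120, max_utr = 2500, seed = 1,
                       strong_signal = FALSE) {
  if (is.null(codon_probs)) {
    codon_probs <- c(AUG = 0.26, CUG = 0.30, GUG = 0.13)
    rest <- setdiff(start_codon_alphabet(), names(codon_probs))
    codon_probs <- c(codon_probs,
                     stats::setNames(rep((1 - sum(codon_probs)) / length(rest),
                                         length(rest)), rest))
  }
  if (strong_signal) {
    kozak_strong <- 1
    context_motif_prob <- 1
  }
  stopifnot(abs(sum(codon_probs) - 1) < 1e-6, abs(sum(bg) - 1) < 1e-6,
            min_utr >= 120)
  structure(
    list(n_transcripts = n_transcripts, carrier_fraction = carrier_fraction,
         true_starts_rate = true_starts_rate,
         utr_mean_true = utr_mean_true, utr_sd_true = utr_sd_true,
         utr_mean_false = utr_mean_false, utr_sd_false = utr_sd_false,
         codon_probs = codon_probs, kozak_strong = kozak_strong,
         context_motif_prob = context_motif_prob, bg = bg[NT],
         cds_codons_range = cds_codons_range,
         ortholog_mutation_rate = ortholog_mutation_rate,
         codon_conserved_prob = codon_conserved_prob,
         min_utr = min_utr, max_utr = max_utr, seed = seed),
    class = "tis_sim_params"
  )
}

rlnorm_moments <- function(n, m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Random CDS: starts with AUG, no premature in-frame stop, terminal stop.
random_cds <- function(n_codons) {
  cods <- setdiff(all_codons(), STOP_CODONS)
  body <- sample(cods, n_codons - 1L, replace = TRUE)
  paste0("AUG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a synthetic transcript corpus
#'
#' Builds primary transcripts (random 5' UTR + structured CDS), plants true
#' start sites with enriched flanking contexts and a guaranteed downstream
#' in-frame stop, derives per-base-mutated ortholog copies, and returns the
#' reported start-site table listing exactly the planted starts. With a
#' `dir`, all five standard files are written (transcript FASTA with
#' `cds_start` header tags, annotation TSV, reported-TIS TSV, ortholog
#' FASTA, pairing TSV); output is byte-identical under a fixed seed.
#'
#' @param params [sim_params()].
#' @param dir Optional output directory (created if needed).
#' @return List: `transcripts`, `orthologs` (named lists of
#'   [transcript()]), `reported`, `pairing` (data frames), `params`, and
#'   `paths` when `dir` was given.
#' @export
generate_dataset <- function(params = sim_params(), dir = NULL) {
  set.seed(params$seed)
  n <- params$n_transcripts
  txs <- list()
  orths <- list()
  rep_rows <- list()
  for (t in seq_len(n)) {
    id <- sprintf("tx%04d", t)
    carrier <- stats::runif(1) < params$carrier_fraction
    m <- if (carrier) params$utr_mean_true else params$utr_mean_false
    s <- if (carrier) params$utr_sd_true else params$utr_sd_false
    utr_len <- round(rlnorm_moments(1, m, s))
    utr_len <- max(params$min_utr, min(params$max_utr, utr_len))
    utr <- paste(sample(NT, utr_len, replace = TRUE, prob = params$bg),
                 collapse = "")
    n_cod <- sample(params$cds_codons_range[1]:params$cds_codons_range[2], 1L)
    seq_full <- paste0(utr, random_cds(n_cod))
    cds_start <- utr_len + 1L
    if (carrier) {
      k <- 1L + stats::rpois(1, params$true_starts_rate)
      lo <- 100L                      # leaves the 99-nt upstream flank
      hi <- utr_len - 9L              # keeps context edits inside the UTR
      picked <- integer(0)
      for (j in seq_len(k)) {
        avail <- setdiff(lo:hi, unlist(lapply(picked, function(p) (p - 34L):(p + 34L))))
        if (!length(avail)) break
        picked <- c(picked, if (length(avail) == 1L) avail else sample(avail, 1L))
      }
      for (i0 in sort(picked)) {
        codon <- sample(names(params$codon_probs), 1L,
                        prob = params$codon_probs)
        substr(seq_full, i0, i0 + 2L) <- codon
        if (stats::runif(1) < params$context_motif_prob) {
          substr(seq_full, i0 - 6L, i0 - 1L) <- "GCCACC"
        }
        if (stats::runif(1) < params$kozak_strong) {
          substr(seq_full, i0 - 3L, i0 - 3L) <- sample(c("A", "G"), 1L)
          substr(seq_full, i0 + 3L, i0 + 3L) <- "G"
        }
        if (orf_length_at(seq_full, i0) == 0L) {
          s0 <- cds_start + 3L
          s0 <- s0 + (i0 - s0) %% 3L   # first in-candidate-frame CDS index
          substr(seq_full, s0, s0 + 2L) <- "UAA"
        }
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          transcript_id = id, position = i0 - cds_start,
          codon = substr(seq_full, i0, i0 + 2L), stringsAsFactors = FALSE
        )
      }
    }
    txs[[id]] <- transcript(id, seq_full, cds_start)
    # ortholog: per-base substituted copy, planted codons optionally restored
    ch <- strsplit(seq_full, "", fixed = TRUE)[[1]]
    mut <- stats::runif(length(ch)) < params$ortholog_mutation_rate
    ch[mut] <- vapply(ch[mut], function(x) sample(setdiff(NT, x), 1L), "")
    if (carrier && length(rep_rows)) {
      mine <- Filter(function(r) r$transcript_id == id, rep_rows)
      for (r in mine) {
        if (stats::runif(1) < params$codon_conserved_prob) {
          i0 <- cds_start + r$position
          ch[i0:(i0 + 2L)] <- strsplit(r$codon, "", fixed = TRUE)[[1]]
        }
      }
    }
    orths[[paste0(id, "_orth")]] <- transcript(paste0(id, "_orth"),
                                               paste(ch, collapse = ""),
                                               cds_start)
  }
  reported <- if (length(rep_rows)) do.call(rbind, rep_rows) else {
    data.frame(transcript_id = character(), position = integer(),
               codon = character(), stringsAsFactors = FALSE)
  }
  ids <- if (is.null(names(txs))) character(0) else names(txs)
  pairing <- data.frame(primary_id = ids,
                        ortholog_id = paste0(ids, "_orth")[seq_along(ids)],
                        stringsAsFactors = FALSE)
  out <- list(transcripts = txs, orthologs = orths, reported = reported,
              pairing = pairing, params = params)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      transcripts = file.path(dir, "transcripts.fasta"),
      annotation = file.path(dir, "annotation.tsv"),
      reported = file.path(dir, "reported_tis.tsv"),
      orthologs = file.path(dir, "orthologs.fasta"),
      pairing = file.path(dir, "pairing.tsv")
    )
    write_tx_fasta(txs, paths$transcripts)
    utils::write.table(
      data.frame(transcript_id = ids,
                 cds_start = vapply(txs, `[[`, 0L, "cds_start",
                                    USE.NAMES = FALSE)),
      paths$annotation, sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(reported, paths$reported, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_tx_fasta(orths, paths$orthologs)
    utils::write.table(pairing, paths$pairing, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

write_tx_fasta <- function(txs, path) {
  lines <- unlist(lapply(txs, function(tx) {
    c(paste0(">", tx$id, " cds_start=", tx$cds_start), tx$sequence)
  }), use.names = FALSE)
  if (is.null(lines)) lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a stand-in flanking-context efficiency table
#'
#' Assigns every possible 11-nt context (-6..+5 around an AUG) an efficiency
#' drawn from a parametric rule: `base` plus `bonus_minus3` for a purine at
#' -3 plus `bonus_plus4` for G at +4 plus Gaussian noise, clipped to
#' [0, 150]. Deterministic under the seed.
#'
#' @param seed RNG seed.
#' @param base Baseline efficiency.
#' @param bonus_minus3,bonus_plus4 Context bonuses.
#' @param noise_sd Gaussian noise SD.
#' @return Data frame `context`, `efficiency` (4^8 = 65,536 rows); pass to
#'   [read_efficiency_table()] or write as TSV.
#' @export
generate_efficiency_table <- function(seed = 1, base = 60, bonus_minus3 = 15,
                                      bonus_plus4 = 10, noise_sd = 8) {
  set.seed(seed)
  g <- do.call(expand.grid, c(rep(list(NT), 8), stringsAsFactors = FALSE))
  names(g) <- c(paste0("m", 6:1), "p4", "p5")  # -6..-1, +4, +5
  ctx <- paste0(g$m6, g$m5, g$m4, g$m3, g$m2, g$m1, "AUG", g$p4, g$p5)
  eff <- base + bonus_minus3 * (g$m3 %in% c("A", "G")) +
    bonus_plus4 * (g$p4 == "G") + stats::rnorm(length(ctx), 0, noise_sd)
  data.frame(context = ctx, efficiency = pmin(pmax(eff, 0), 150),
             stringsAsFactors = FALSE)
}

#' Run the whole pipeline on a synthetic corpus
#'
#' Generates data, enumerates and labels candidates, aligns orthologs,
#' extracts features and runs the repeated training experiment; the
#' integration fixture used in tests and documentation.
#'
#' @param params [sim_params()].
#' @param config [training_config()].
#' @param efficiency Optional `tis_efficiency`; generated from the params
#'   seed when omitted.
#' @param use_orthologs Compute conservation features (default `TRUE`).
#' @param max_false Optional cap on the number of labeled false starts kept
#'   before feature extraction (subsampled reproducibly; keeps large-corpus
#'   experiments tractable).
#' @return List: `experiment` (a `tis_experiment`), `dataset`, `candidates`,
#'   `generated`.
#' @export
end_to_end_fixture <- function(params = sim_params(),
                               config = training_config(),
                               efficiency = NULL, use_orthologs = TRUE,
                               max_false = NULL) {
  gen <- generate_dataset(params)
  if (is.null(efficiency)) {
    efficiency <- read_efficiency_table(generate_efficiency_table(params$seed))
  }
  cands <- do.call(rbind, lapply(gen$transcripts, enumerate_candidates))
  cands <- label_candidates(cands, gen$reported)
  if (!is.null(max_false)) {
    idx_f <- which(cands$label == "FALSE_START")
    if (length(idx_f) > max_false) {
      set.seed(params$seed + 1L)
      drop <- setdiff(idx_f, sample(idx_f, max_false))
      cands$label[drop] <- "EXCLUDED"
    }
  }
  pairs <- if (use_orthologs) {
    build_pairs(gen$transcripts, gen$orthologs, gen$pairing)
  } else NULL
  dataset <- build_dataset(gen$transcripts, cands, pairs, efficiency)
  experiment <- run_experiment(dataset, config)
  list(experiment = experiment, dataset = dataset, candidates = cands,
       generated = gen)
}
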