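# Feature registry and small sequence utilities shared across modules.

NT <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Near-cognate start-codon alphabet
#'
#' AUG plus the nine triplets that differ from AUG by exactly one nucleotide.
#' Candidate enumeration is restricted to this ten-codon alphabet.
#'
#' @return Character vector of length 10.
#' @export
start_codon_alphabet <- function() {
  c("AUG", "CUG", "UUG", "GUG", "AAG", "ACG", "AGG", "AUA", "AUC", "AUU")
}

# All 64 RNA triplets in lexicographic (A < C < G < U) order.
all_codons <- function() {
  g <- expand.grid(n3 = NT, n2 = NT, n1 = NT, stringsAsFactors = FALSE)
  paste0(g$n1, g$n2, g$n3)
}

# One-letter -> three-letter amino-acid names (20 standard residues).
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

# RNA codon -> one-letter residue ("*" for stops), standard genetic code.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  gc
}

#' Translate an RNA string with the standard genetic code
#'
#' Trailing incomplete codons are dropped; stop codons are rendered as "*"
#' and kept in-line (no truncation at the first stop).
#'
#' @param rna RNA string over A/C/G/U.
#' @param frame 0-based frame offset (0, 1 or 2).
#' @return Single amino-acid string, possibly empty.
#' @export
translate_rna <- function(rna, frame = 0) {
  n <- nchar(rna)
  if (n - frame < 3) return("")
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  cods <- substring(rna, starts, starts + 2L)
  paste(codon_table()[cods], collapse = "")
}

# k-mer region identifiers, in registry order.
KMER_REGIONS5 <- c("all", "up", "down", "inframe_up", "inframe_down")
KMER_REGIONS3 <- c("all", "up", "down")

#' Feature registry
#'
#' Enumerates the full, ordered feature space used throughout the package:
#' 3 position-weight-matrix scores, 20 biologically motivated features, and
#' 1,229 k-mer features (792 position-specific single-nucleotide indicators,
#' 320 codon counts, 100 amino-acid counts, 5 stop-codon counts and 12
#' mononucleotide counts), 1,252 features in total.
#'
#' @param window Flank length in nt on each side of the candidate codon used
#'   for the position-specific k-mers (default 99; all published counts
#'   assume 99).
#' @return Named list with one character vector of feature names per family
#'   (`pwm`, `biological`, `kmer_pos`, `kmer_codon`, `kmer_aa`, `kmer_stop`,
#'   `kmer_nt`) plus `all`, the concatenation in canonical order.
#' @export
feature_registry <- function(window = 99) {
  pwm <- c("pwm_pos_score", "pwm_neg_score", "pwm_ratio_score")
  biological <- c(
    "utr_length", "utr_conservation", "codon_conserved", "aa_conserved",
    "in_frame", "kozak_class", "context_efficiency",
    "mfe_p14", "mfe_p20", "mfe_m10p50", "mfe_m50p50",
    "gc_p14", "gc_p20", "gc_m10p50", "gc_m50p50",
    "orf_length_nt", "utr_frac_A", "utr_frac_C", "utr_frac_G", "utr_frac_U"
  )
  # Kozak-style positions: upstream -window..-1, codon occupies +1..+3
  # (never position-indexed), downstream +4..+(window+3).
  pos <- c(-window:-1, 4:(window + 3))
  kmer_pos <- as.vector(t(outer(pos, NT, function(p, n) {
    paste0("kmer:pos:", p, ":", n)
  })))
  kmer_codon <- as.vector(t(outer(KMER_REGIONS5, all_codons(), paste, sep = ":")))
  kmer_codon <- paste0("kmer:", kmer_codon)
  kmer_aa <- as.vector(t(outer(KMER_REGIONS5, unname(AA3), paste, sep = ":")))
  kmer_aa <- paste0("kmer:", kmer_aa)
  kmer_stop <- paste0("kmer:", KMER_REGIONS5, ":stop")
  kmer_nt <- as.vector(t(outer(KMER_REGIONS3, NT, paste, sep = ":")))
  kmer_nt <- paste0("kmer:", kmer_nt)
  fam <- list(
    pwm = pwm, biological = biological, kmer_pos = kmer_pos,
    kmer_codon = kmer_codon, kmer_aa = kmer_aa, kmer_stop = kmer_stop,
    kmer_nt = kmer_nt
  )
  fam$all <- unlist(fam, use.names = FALSE)
  fam
}

# Names of the features recomputed from training data in every repetition.
pwm_feature_names <- function() c("pwm_pos_score", "pwm_neg_score", "pwm_ratio_score")

# Ensure a string is RNA over {A,C,G,U}; DNA input (T) is converted.
as_rna <- function(x) {
  x <- chartr("tT", "uU", toupper(x))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,U,T}: ",
         paste(utils::head(which(bad)), collapse = ", "))
  }
  x
}

# Nucleotide counts of a string, in A,C,G,U order.
nt_counts <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  tab <- tabulate(match(ch, NT), nbins = 4L)
  names(tab) <- NT
  tab
}
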