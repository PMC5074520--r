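# Independent brute-force oracles. Each re-derives a quantity with a
# different algorithm than the implementation (naive counting, explicit
# structure enumeration, permutation enumeration), so agreement is a real
# cross-check, not a restatement.

# --- candidate enumeration -------------------------------------------------
# Naive re-scan: loop over every UTR offset, re-check each condition with
# string operations only.
oracle_enumerate <- function(tx, window = 99) {
  out <- list()
  n <- nchar(tx$sequence)
  alphabet <- c("AUG", "CUG", "UUG", "GUG", "AAG", "ACG", "AGG",
                "AUA", "AUC", "AUU")
  for (i in seq_len(max(0, tx$cds_start - 3))) {
    cod <- substr(tx$sequence, i, i + 2)
    if (!cod %in% alphabet) next
    if (i - 1 < window || n - (i + 2) < window) next
    stop_at <- NA
    j <- i + 3
    while (j + 2 <= n) {
      if (substr(tx$sequence, j, j + 2) %in% c("UAA", "UAG", "UGA")) {
        stop_at <- j
        break
      }
      j <- j + 3
    }
    if (is.na(stop_at)) next
    out[[length(out) + 1]] <- data.frame(
      transcript_id = tx$id, position = i - tx$cds_start, codon = cod,
      frame = if ((i - tx$cds_start) %% 3 == 0) "in_frame" else "out_of_frame",
      orf_length_nt = stop_at + 2 - i + 1, label = "EXCLUDED",
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# --- PWM -------------------------------------------------------------------
# Direct per-cell counting and literal log formulas.
oracle_pwm <- function(true_ctx, false_ctx, bg, pseudocount = 0.5) {
  w <- nchar(true_ctx[1])
  count <- function(ctxs) {
    m <- matrix(0, 4, w, dimnames = list(NTS, NULL))
    for (s in ctxs) {
      for (i in 1:w) {
        nt <- substr(s, i, i)
        m[nt, i] <- m[nt, i] + 1
      }
    }
    (m + pseudocount) / (length(ctxs) + 4 * pseudocount)
  }
  pfm_p <- count(true_ctx)
  pfm_n <- count(false_ctx)
  list(pfm_pos = pfm_p, pfm_neg = pfm_n,
       pwm_pos = log(sweep(pfm_p, 1, bg[NTS], "/")),
       pwm_neg = log(sweep(pfm_n, 1, bg[NTS], "/")),
       pwm_ratio = log(pfm_p / pfm_n))
}

oracle_pwm_score <- function(ctx, m) {
  s <- 0
  for (i in seq_len(nchar(ctx))) s <- s + m[substr(ctx, i, i), i]
  unname(s)
}

# --- folding ---------------------------------------------------------------
# Exhaustive enumeration of every non-crossing pairing with a minimum
# hairpin loop of 3; returns the minimum total pair energy.
oracle_mfe <- function(s, minloop = 3) {
  ch <- strsplit(s, "")[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(-1)
    NA
  }
  structures <- function(i, j) {
    if (j - i < minloop + 1) return(list(list()))
    out <- lapply(structures(i, j - 1), identity)     # j unpaired
    for (k in i:(j - minloop - 1)) {
      if (is.na(w(ch[k], ch[j]))) next
      left <- if (k > i) structures(i, k - 1) else list(list())
      inside <- structures(k + 1, j - 1)
      for (L in left) for (I in inside) {
        out[[length(out) + 1]] <- c(L, I, list(c(k, j)))
      }
    }
    out
  }
  energies <- vapply(structures(1, length(ch)), function(st) {
    if (!length(st)) return(0)
    sum(vapply(st, function(p) w(ch[p[1]], ch[p[2]]), numeric(1)))
  }, numeric(1))
  min(energies)
}

# --- k-mers ----------------------------------------------------------------
# Naive sliding-window recount of all 1,229 slots.
oracle_kmers <- function(up, codon, down) {
  window <- nchar(up)
  complete <- paste0(up, codon, down)
  slide <- function(x, stride = 1) {
    if (nchar(x) < 3) return(character(0))
    starts <- seq(1, nchar(x) - 2, by = stride)
    vapply(starts, function(i) substr(x, i, i + 2), "")
  }
  regions <- list(all = slide(complete), up = slide(up), down = slide(down),
                  inframe_up = slide(up, 3), inframe_down = slide(down, 3))
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val")
  out <- numeric(0)
  flank_chars <- strsplit(paste0(up, down), "")[[1]]
  pos_lab <- c(-window:-1, 4:(window + 3))
  for (i in seq_along(flank_chars)) {
    for (nt in NTS) {
      out[paste0("kmer:pos:", pos_lab[i], ":", nt)] <-
        as.numeric(flank_chars[i] == nt)
    }
  }
  codons64 <- apply(expand.grid(NTS, NTS, NTS)[, 3:1], 1, paste, collapse = "")
  for (r in names(regions)) {
    for (cod in codons64) {
      out[paste0("kmer:", r, ":", cod)] <- sum(regions[[r]] == cod)
    }
  }
  for (r in names(regions)) {
    for (a in names(aa3)) {
      out[paste0("kmer:", r, ":", aa3[[a]])] <-
        sum(gc[regions[[r]]] == a, na.rm = TRUE)
    }
  }
  for (r in names(regions)) {
    out[paste0("kmer:", r, ":stop")] <-
      sum(regions[[r]] %in% c("UAA", "UAG", "UGA"))
  }
  for (r in c("all", "up", "down")) {
    x <- switch(r, all = complete, up = up, down = down)
    for (nt in NTS) {
      out[paste0("kmer:", r, ":", nt)] <-
        lengths(regmatches(x, gregexpr(nt, x, fixed = TRUE)))
    }
  }
  out
}

# --- rank-sum test ---------------------------------------------------------
# Exact two-sided p by complete enumeration of the permutation distribution
# of the Mann-Whitney U statistic (tie-free data).
oracle_ranksum_p <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  pooled <- c(x1, x0)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n0, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# --- threshold metrics -----------------------------------------------------
# Literal confusion recount at one threshold.
oracle_metrics <- function(conf, labels, t) {
  TP <- 0; FP <- 0; TN <- 0; FN <- 0
  for (i in seq_along(conf)) {
    pos <- conf[i] >= t
    if (pos && labels[i] == 1) TP <- TP + 1
    if (pos && labels[i] == 0) FP <- FP + 1
    if (!pos && labels[i] == 0) TN <- TN + 1
    if (!pos && labels[i] == 1) FN <- FN + 1
  }
  c(TP = TP, FP = FP, TN = TN, FN = FN,
    accuracy = (TP + TN) / length(conf),
    sensitivity = TP / (TP + FN), specificity = TN / (TN + FP))
}

# AUC as the fraction of (positive, negative) pairs ranked correctly
# (ties count one half).
oracle_auc <- function(conf, labels) {
  pos <- conf[labels == 1]; neg <- conf[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
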