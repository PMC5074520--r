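test_that("feature registry enumerates the documented feature space", {
  reg <- feature_registry()
  expect_length(reg$pwm, 3)
  expect_length(reg$biological, 20)
  expect_length(reg$kmer_pos, 792)
  expect_length(reg$kmer_codon, 320)
  expect_length(reg$kmer_aa, 100)
  expect_length(reg$kmer_stop, 5)
  expect_length(reg$kmer_nt, 12)
  expect_length(reg$all, 1252)
  expect_false(anyDuplicated(reg$all) > 0)
  expect_true("kmer:pos:-12:C" %in% reg$all)     # Table-style slot names
  expect_true("kmer:up:AUG" %in% reg$all)
  expect_true("kmer:inframe_up:Met" %in% reg$all)
  expect_true("kmer:down:stop" %in% reg$all)
})

test_that("PWM construction follows the log-frequency-over-background formula", {
  bg <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  # symmetric contexts: every nucleotide once per column -> all entries 0
  ctx <- c("AC", "CG", "GU", "UA")
  m <- build_pwm_model(ctx, ctx, bg)
  expect_equal(unname(m$pwm_pos), matrix(0, 4, 2), tolerance = 1e-12)
  expect_equal(unname(m$pwm_ratio), matrix(0, 4, 2), tolerance = 1e-12)

  # an all-C column with vanishing pseudocount approaches ln(1/0.25) = ln 4
  m <- build_pwm_model(c("C", "C", "C"), c("A", "C", "G"), bg,
                       pseudocount = 1e-9)
  expect_equal(unname(m$pwm_pos["C", 1]), log(4), tolerance = 1e-6)

  expect_error(build_pwm_model("AC", "AC", c(A = 0.5, C = 0.5, G = 0, U = 0)),
               "zero background")
  expect_error(build_pwm_model(c("AC", "ACG"), "AC", bg), "identical length")
})

test_that("PWM matrices and scores match the brute-force counting oracle", {
  set.seed(5)
  true_ctx <- replicate(6, paste(sample(NTS, 8, TRUE), collapse = ""))
  false_ctx <- replicate(6, paste(sample(NTS, 8, TRUE,
                                         prob = c(.4, .1, .3, .2)), collapse = ""))
  bg <- c(A = 0.2, C = 0.3, G = 0.3, U = 0.2)
  m <- build_pwm_model(true_ctx, false_ctx, bg)
  o <- oracle_pwm(true_ctx, false_ctx, bg)
  expect_equal(unname(m$pfm_pos), unname(o$pfm_pos), tolerance = 1e-12)
  expect_equal(unname(m$pwm_pos), unname(o$pwm_pos), tolerance = 1e-12)
  expect_equal(unname(m$pwm_neg), unname(o$pwm_neg), tolerance = 1e-12)
  expect_equal(unname(m$pwm_ratio), unname(o$pwm_ratio), tolerance = 1e-12)
  # structural identities
  expect_equal(colSums(m$pfm_pos), rep(1, 8), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$pwm_ratio, m$pwm_pos - m$pwm_neg, tolerance = 1e-12)
  for (cx in c(true_ctx, false_ctx)) {
    expect_equal(pwm_score(cx, m$pwm_pos), oracle_pwm_score(cx, m$pwm_pos))
    expect_equal(pwm_score(cx, m$pwm_ratio), oracle_pwm_score(cx, m$pwm_ratio))
  }
})

test_that("pwm_score sums matrix entries over the window", {
  m <- matrix(0, 4, 2, dimnames = list(NTS, NULL))
  expect_equal(pwm_score("GU", m), 0)
  m["A", 1] <- 1.0
  m["C", 2] <- -0.5
  expect_equal(pwm_score("AC", m), 0.5)
  expect_error(pwm_score("ACG", m), "does not match")
})

test_that("the consensus context scores at least as high as any point variant", {
  ctx <- rep("ACGUACGU", 10)
  m <- build_pwm_model(ctx, rep("UUUUUUUU", 10),
                       c(A = .25, C = .25, G = .25, U = .25),
                       pseudocount = 1e-9)
  cons_score <- pwm_score("ACGUACGU", m$pwm_pos)
  for (i in 1:8) {
    for (nt in setdiff(NTS, substr("ACGUACGU", i, i))) {
      v <- "ACGUACGU"
      substr(v, i, i) <- nt
      expect_lte(pwm_score(v, m$pwm_pos), cons_score)
    }
  }
})

test_that("Kozak context classes follow the -3/+4 rule", {
  expect_equal(kozak_class("A", "G"), 4L)   # strong
  expect_equal(kozak_class("G", "A"), 3L)   # intermediate
  expect_equal(kozak_class("C", "G"), 2L)   # weak
  expect_equal(kozak_class("U", "U"), 1L)   # no context
  expect_equal(kozak_class(c("A", "C"), c("G", "G")), c(4L, 2L))
})

test_that("context efficiency looks up the AUG-substituted -6..+5 context", {
  tx <- planted_cug_tx()
  cand <- enumerate_candidates(tx)[1, ]
  i0 <- tx$cds_start + cand$position
  ctx <- substr(tx$sequence, i0 - 6, i0 + 4)
  substr(ctx, 7, 9) <- "AUG"
  eff <- read_efficiency_table(
    data.frame(context = ctx, efficiency = 83.0)
  )
  expect_equal(context_efficiency(tx, cand, eff), 83.0)

  # a near-cognate start scores identically to an AUG with the same flanks
  tx_aug <- transcript("aug", plant(tx$sequence, i0, "AUG"), tx$cds_start)
  expect_equal(context_efficiency(tx_aug, cand, eff), 83.0)

  miss <- read_efficiency_table(
    data.frame(context = c("AAAAAAAUGAA", "GGGGGGAUGGG"),
               efficiency = c(40, 60))
  )
  expect_warning(v <- context_efficiency(tx, cand, miss), "absent")
  expect_equal(v, 50.0)
})

test_that("GC and folding-energy windows behave as specified", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AAUU"), 0.0)
  expect_equal(mfe_nussinov(strrep("A", 40)), 0.0)
  # exhaustive structure enumeration oracle on short RNAs
  expect_equal(mfe_nussinov("GGGGAAAACCCC"), oracle_mfe("GGGGAAAACCCC"))
  set.seed(8)
  for (k in 1:6) {
    s <- paste(sample(NTS, 12, TRUE), collapse = "")
    expect_equal(mfe_nussinov(s), oracle_mfe(s), info = s)
  }
  # window layout: four windows, truncation flagged at transcript edges
  tx <- planted_cug_tx()
  cand <- enumerate_candidates(tx)[1, ]
  wf <- window_features(tx, cand)
  expect_named(wf$mfe, c("p14", "p20", "m10p50", "m50p50"))
  expect_true(all(wf$mfe <= 0))
  expect_false(any(wf$truncated))
  i0 <- tx$cds_start + cand$position
  expect_equal(unname(wf$gc["m50p50"]),
               gc_content(substr(tx$sequence, i0 - 50, i0 + 49)))
  expect_equal(unname(wf$gc["p14"]),
               gc_content(substr(tx$sequence, i0 + 13, i0 + 72)))
})

test_that("5' UTR composition features are exact fractions", {
  expect_equal(unname(utr_stats(make_tx("ACGU", "AUGUAA"))),
               c(4, .25, .25, .25, .25))
  expect_equal(unname(utr_stats(make_tx("GGGG", "AUGUAA"))),
               c(4, 0, 0, 1, 0))
  set.seed(12)
  utr <- paste(sample(NTS, 100, TRUE), collapse = "")
  st <- utr_stats(make_tx(utr, "AUGUAA"))
  ch <- strsplit(utr, "")[[1]]
  expect_equal(unname(st["frac_G"]), sum(ch == "G") / 100)
  expect_equal(sum(st[paste0("frac_", NTS)]), 1)
})

test_that("k-mer counting is overlapping and frame-locked where documented", {
  # window = 6 toy: upstream flank AUGAUG holds two overlapping AUGs
  utr <- paste0("AUGAUG", "CUG", "AUGGCC", strrep("C", 100))
  tx <- make_tx(utr, paste0("AUG", strrep("GCA", 50), "UAA"))
  cand <- data.frame(transcript_id = tx$id, position = 7L - tx$cds_start,
                     codon = "CUG")
  v <- kmer_features(tx, cand, window = 6)
  expect_equal(unname(v["kmer:up:AUG"]), 2)
  expect_equal(unname(v["kmer:inframe_up:AUG"]), 2)      # stride 3 tiles AUG|AUG
  expect_equal(unname(v["kmer:down:AUG"]), 1)
  # the four indicators of any one position sum to 1
  pos_block <- v[grep("^kmer:pos:-3:", names(v))]
  expect_equal(sum(pos_block), 1)
})

test_that("all 1,229 k-mer slots equal a naive sliding-window recount", {
  tx <- random_tx(31, utr_len = 320)
  cands <- enumerate_candidates(tx)
  cand <- cands[which.min(cands$position), ]
  i0 <- tx$cds_start + cand$position
  up <- substr(tx$sequence, i0 - 99, i0 - 1)
  down <- substr(tx$sequence, i0 + 3, i0 + 101)
  got <- kmer_features(tx, cand)
  want <- oracle_kmers(up, cand$codon, down)
  expect_length(got, 1229)
  expect_equal(got[names(want)], want)
})

test_that("the assembled feature vector is complete, deterministic and self-consistent", {
  tx <- random_tx(17, utr_len = 300)
  cands <- enumerate_candidates(tx)
  cand <- cands[1, ]
  eff <- full_efficiency()
  pair <- align_orthologs(tx, tx)
  set.seed(2)
  ctxs <- replicate(8, paste(sample(NTS, 28, TRUE), collapse = ""))
  pwm <- build_pwm_model(ctxs[1:4], ctxs[5:8],
                         c(A = .25, C = .25, G = .25, U = .25))
  v1 <- extract_features(tx, cand, pair, eff, pwm)
  v2 <- extract_features(tx, cand, pair, eff, pwm)
  expect_length(v1, 1252)
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_registry()$all)
  expect_false(anyNA(v1))
  # amino-acid counts are sums of their codon counts; stops likewise
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  for (r in c("all", "up", "inframe_down")) {
    leu <- sum(v1[paste0("kmer:", r, ":", names(gc)[gc == "L"])])
    expect_equal(unname(v1[paste0("kmer:", r, ":Leu")]), leu)
    st <- sum(v1[paste0("kmer:", r, ":", c("UAA", "UAG", "UGA"))])
    expect_equal(unname(v1[paste0("kmer:", r, ":stop")]), st)
  }
  # GC of a window is 1 - (A+U fraction) of that window
  i0 <- tx$cds_start + cand$position
  w <- substr(tx$sequence, i0 + 13, i0 + 72)
  ch <- strsplit(w, "")[[1]]
  expect_equal(unname(v1["gc_p14"]), 1 - mean(ch %in% c("A", "U")))
  # k-mer slots are non-negative integers
  km <- v1[grep("^kmer:", names(v1))]
  expect_true(all(km >= 0 & km == round(km)))
})
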