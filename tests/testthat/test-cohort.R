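test_that("paired precision matches sign agreement with the gold standard", {
  calls <- data.frame(site_id = c("c1", "c2", "c3", "c4"),
                      direction = c("hyper", "hyper", "hypo", "hypo"))
  tb <- c(c1 = 0.9, c2 = 0.8, c3 = 0.1, c4 = 0.5)
  nb <- c(c1 = 0.5, c2 = 0.4, c3 = 0.6, c4 = 0.2)   # c4 contradicts "hypo"
  r <- precision_against_paired(calls, tb, nb)
  expect_equal(r$tp, 3L); expect_equal(r$fp, 1L)
  expect_equal(r$precision, 0.75)

  all_ok <- precision_against_paired(calls[1:3, ], tb, nb)
  expect_equal(all_ok$precision, 1)

  # zero observed difference counts as FP; missing sites are excluded
  tb2 <- c(c1 = 0.5, c2 = 0.8, c4 = 0.1)
  nb2 <- c(c1 = 0.5, c2 = 0.4, c4 = 0.6)
  r2 <- precision_against_paired(calls, tb2, nb2)
  expect_equal(r2$excluded, 1L)                       # c3 unmeasured
  expect_equal(r2$tp, 2L)                             # c2 hyper, c4 hypo
  expect_equal(r2$fp, 1L)                             # c1 tie -> FP
  expect_equal(r2$tp + r2$fp + r2$excluded, nrow(calls))

  none <- precision_against_paired(calls[0, ], tb, nb)
  expect_true(is.na(none$precision))

  restr <- precision_against_paired(calls, tb, nb, restrict_to = c("c1", "c4"))
  expect_equal(restr$tp + restr$fp, 2L)
})

test_that("paired precision equals a direct recount on simulated truth", {
  st <- run_recovery_study(seed = 77)
  s <- "T003"
  calls <- st$calls[st$calls$sample_id == s, ]
  # a synthetic "paired normal": the baseline; tumour: its own profile
  tb <- unclass(st$tumor$beta)[, s]
  nb <- attr(st$normal, "baseline")
  r <- precision_against_paired(calls, tb, nb)
  naive_tp <- sum(vapply(seq_len(nrow(calls)), function(k) {
    d <- tb[calls$site_id[k]] - nb[calls$site_id[k]]
    (calls$direction[k] == "hyper" && d > 0) ||
      (calls$direction[k] == "hypo" && d < 0)
  }, logical(1)))
  expect_equal(r$tp, naive_tp)
  expect_equal(r$tp + r$fp + r$excluded, nrow(calls))
})

test_that("aberration recurrence uses strict inequality at the cutoff", {
  calls <- rbind(
    data.frame(sample_id = sprintf("t%02d", 1:10), site_id = "c1",
               direction = "hyper"),
    data.frame(sample_id = sprintf("t%02d", 1:9), site_id = "c2",
               direction = "hyper"),
    data.frame(sample_id = sprintf("t%02d", 1:3), site_id = "c3",
               direction = "hypo"))
  r <- aberration_frequency(calls, n_samples = 10, min_frequency = 0.9)
  expect_equal(r$frequencies$hyper_frequency[r$frequencies$site_id == "c1"], 1)
  expect_equal(r$recurrent$site_id, "c1")          # 9/10 = 0.9 is excluded
  expect_equal(r$recurrent$direction, "hyper")
  expect_true(all(r$frequencies$hyper_frequency +
                  r$frequencies$hypo_frequency <= 1))

  r2 <- aberration_frequency(calls, n_samples = 10, min_frequency = 0.2)
  expect_setequal(r2$recurrent$site_id, c("c1", "c2", "c3"))
})

test_that("a universal injected aberration is the recurrent one", {
  cfg <- sim_config(n_sites = 100, n_normals = 40, n_tumors = 15,
                    dm_fraction = 0.01, recurrence = 1, seed = 104)
  norm <- simulate_normal_cohort(cfg)
  bg <- rmo_background(norm)
  tum <- simulate_tumor_cohort(cfg, norm)
  expect_equal(nrow(tum$registry), 1L)
  expect_equal(nrow(tum$truth), 15L)            # fires in every tumour
  calls <- predict(bg, tum$beta, fdr_threshold = 0.01)
  rec <- aberration_frequency(calls, n_samples = 15, min_frequency = 0.9)
  expect_true(tum$registry$site_id %in% rec$recurrent$site_id)
})

test_that("paired direction frequency reproduces printed-table arithmetic", {
  # 7 of 8 pairs tumour-higher -> 87.5%
  tb <- matrix(c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.1), 1,
               dimnames = list("cg19466563", sprintf("p%d", 1:8)))
  nb <- matrix(0.5, 1, 8, dimnames = dimnames(tb))
  r <- paired_direction_frequency("cg19466563", methyl_matrix(tb),
                                  methyl_matrix(nb))
  expect_equal(100 * r$frac_higher, 87.50)
  # 8 of 8 -> 100%
  tb2 <- tb; tb2[1, 8] <- 0.9
  r2 <- paired_direction_frequency("cg19466563", methyl_matrix(tb2),
                                   methyl_matrix(nb))
  expect_equal(100 * r2$frac_higher, 100)
  # ties count toward neither direction
  r3 <- paired_direction_frequency("cg19466563", methyl_matrix(nb),
                                   methyl_matrix(nb))
  expect_equal(r3$frac_higher, 0); expect_equal(r3$frac_lower, 0)
  # all-missing site: explicit absent result
  tbNA <- tb; tbNA[1, ] <- NA
  r4 <- paired_direction_frequency("cg19466563", methyl_matrix(tbNA),
                                   methyl_matrix(nb))
  expect_equal(r4$n_pairs, 0L); expect_true(is.na(r4$frac_higher))
})

test_that("gene status needs >= 1 hyper and 0 hypo promoter calls", {
  ann <- data.frame(site_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
                    gene_symbol = c("G1", "G1", "G2", "G2", "G3", "G4"),
                    promoter_flag = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                    platforms = "27K;450K")
  calls <- data.frame(site_id = c("s1", "s3", "s4", "s6"),
                      direction = c("hyper", "hyper", "hypo", "hyper"))
  st <- gene_methylation_status(calls, ann)
  expect_equal(st$status[st$gene_symbol == "G1"], "hypermethylated")
  expect_equal(st$status[st$gene_symbol == "G2"], "not")  # hypo veto
  expect_equal(st$status[st$gene_symbol == "G3"], "not")  # no call
  expect_false("G4" %in% st$gene_symbol)  # promoter-less gene absent

  # naive per-gene loop oracle on a random configuration
  set.seed(61)
  ann2 <- data.frame(site_id = sprintf("s%03d", 1:60),
                     gene_symbol = sample(sprintf("G%02d", 1:15), 60, TRUE),
                     promoter_flag = sample(c(TRUE, FALSE), 60, TRUE, c(0.8, 0.2)),
                     platforms = "27K;450K")
  calls2 <- data.frame(site_id = sample(ann2$site_id, 25),
                       direction = sample(c("hyper", "hypo"), 25, TRUE))
  got <- gene_methylation_status(calls2, ann2)
  for (g in got$gene_symbol) {
    sites <- ann2$site_id[ann2$gene_symbol == g & ann2$promoter_flag]
    dirs <- calls2$direction[calls2$site_id %in% sites]
    want <- if (sum(dirs == "hyper") >= 1 && sum(dirs == "hypo") == 0)
      "hypermethylated" else "not"
    expect_equal(got$status[got$gene_symbol == g], want)
  }
})

test_that("down-regulation frequency is the strict-less fraction of pairs", {
  expect_equal(100 * downregulation_frequency(rep(1, 8), rep(2, 8))$frac_down,
               100)
  r <- downregulation_frequency(c(1, 2, 3, 3), c(2, 3, 4, 3))
  expect_equal(r$frac_down, 0.75)        # the tied pair is not down
  expect_error(downregulation_frequency(1:3, 1:4), "pair-matched")
  expect_true(is.na(downregulation_frequency(NA, 1)$frac_down))
})

test_that("pathway over-representation matches hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:30)
  paths <- list(P1 = universe[1:5], P2 = universe[10:19], P3 = universe[25:30])
  res <- pathway_enrichment(universe[1:5], paths, universe,
                            fdr_threshold = 0.05)
  expect_equal(res$pathway_id[1], "P1")      # full overlap = smallest p
  expect_equal(res$overlap[res$pathway_id == "P3"], 0L)
  expect_gte(res$p[res$pathway_id == "P3"], 0.05)

  # enumeration oracle: P(overlap >= k) by summing choose() terms
  draw <- universe[c(1:3, 10, 25)]
  got <- pathway_enrichment(draw, paths, universe, fdr_threshold = 0.05)
  for (pw in names(paths)) {
    K <- length(paths[[pw]]); n <- length(draw); N <- length(universe)
    k <- length(intersect(paths[[pw]], draw))
    want <- sum(vapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1)))
    expect_equal(got$p[got$pathway_id == pw], want, tolerance = 1e-12)
  }
  expect_equal(nrow(pathway_enrichment(character(), paths, universe)), 0L)
})

test_that("random gene lists are retained at about the nominal rate or less", {
  set.seed(87)
  universe <- sprintf("g%03d", 1:200)
  paths <- lapply(1:20, function(i) sample(universe, 15))
  names(paths) <- sprintf("P%02d", 1:20)
  hits <- vapply(1:40, function(r) {
    sum(pathway_enrichment(sample(universe, 10), paths, universe,
                           fdr_threshold = 0.05)$significant)
  }, numeric(1))
  expect_lte(mean(hits), 0.05 * 20)
})

test_that("GMT files parse and agree with the reference reader", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("PATH_A\tdesc\tg1\tg2\tg3",
               "PATH_B\thttp://x\tg2\tg4",
               "PATH_C\tdesc\tg5\tg5\tg6"), f)
  g <- read_gmt(f)
  expect_equal(names(g), c("PATH_A", "PATH_B", "PATH_C"))
  expect_equal(g$PATH_C, c("g5", "g6"))          # duplicates collapsed
  ref <- fgsea::gmtPathways(f)
  expect_equal(lapply(g, sort), lapply(ref, function(x) sort(unique(x))))
  writeLines("BROKEN\tonly-two-fields", f)
  expect_error(read_gmt(f), "malformed GMT line 1")
})
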