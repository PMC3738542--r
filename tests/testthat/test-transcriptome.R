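test_that("MA transform matches direct log arithmetic", {
  sp <- make_spots(M = 0, A = 0.5 * log2(1000 * 1000))
  sp$F_ch1 <- 1000; sp$F_ch2 <- 1000
  out <- ma_transform(sp[1, ])
  expect_equal(out$M, 0)
  expect_equal(out$A, log2(1000), tolerance = 1e-12)
  sp2 <- make_spots(M = 2, A = 10)
  out2 <- ma_transform(sp2)
  expect_equal(out2$M, rep(2, nrow(sp2)), tolerance = 1e-12)
  set.seed(3)
  smp <- runif(50, 10, 5e4); rf <- runif(50, 10, 5e4)
  sp3 <- data.frame(block = 1L, probe_id = paste0("p", 1:50),
                    F_ch1 = smp, F_ch2 = rf, sample_ch1 = "s",
                    sample_ch2 = "pool")
  out3 <- ma_transform(sp3)
  expect_equal(out3$M, log2(smp) - log2(rf), tolerance = 1e-12)
  expect_equal(out3$A, (log2(smp) + log2(rf)) / 2, tolerance = 1e-12)
})

test_that("non-positive foreground intensities flag the spot unusable", {
  sp <- make_spots(M = c(0, 0, 0), A = c(10, 10, 10))
  sp$F_ch1[2] <- 0
  sp$F_ch2[3] <- -5
  out <- ma_transform(sp)
  expect_equal(out$usable, c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(out$M[2:3])))
})

test_that("orientation correction makes a dye-swap pair agree in sign", {
  a1 <- ma_transform(make_spots(M = 2, A = 10, swap = FALSE))
  a2 <- ma_transform(make_spots(M = 2, A = 10, swap = TRUE))
  # raw Cy5/Cy3 ratios have opposite signs across the pair
  expect_equal(log2(a1$F_ch1 / a1$F_ch2), rep(2, nrow(a1)))
  expect_equal(log2(a2$F_ch1 / a2$F_ch2), rep(-2, nrow(a2)))
  # oriented sample-over-reference M agrees
  expect_equal(a1$M, a2$M)
  cons <- consolidate_dye_swap(list(a1, a2))
  expect_equal(cons$M, rep(2, nrow(cons)))
})

test_that("dye-swap consolidation averages member estimates per gene", {
  a1 <- ma_transform(make_spots(M = 1.5, A = 10, probe = "g1"))
  a2 <- ma_transform(make_spots(M = 0.5, A = 10, probe = "g1", swap = TRUE))
  cons <- consolidate_dye_swap(list(a1, a2))
  expect_equal(cons$M, 1.0)
  expect_equal(cons$n_arrays, 2)
  # gene missing on one member: kept, flagged by n_arrays
  a3 <- ma_transform(make_spots(M = c(1, 2), A = 10, probe = c("g1", "g2")))
  cons2 <- consolidate_dye_swap(list(a1, a3))
  expect_equal(cons2$n_arrays[cons2$gene_id == "g2"], 1)
})

test_that("print-tip loess removes constant and linear trends per tip", {
  n <- 200
  A <- seq(6, 14, length.out = n)
  sp <- data.frame(block = 1L, probe_id = paste0("p", 1:n), M = 0.7, A = A,
                   usable = TRUE)
  out <- printtip_loess_normalize(sp)
  expect_lt(max(abs(out$M)), 1e-9)
  sp$M <- 0.3 + 0.1 * A
  out2 <- printtip_loess_normalize(sp)
  interior <- A > 7 & A < 13
  expect_lt(max(abs(out2$M[interior])), 1e-6)
})

test_that("tips are normalized independently", {
  n <- 100
  A <- runif(n, 6, 14)
  sp <- data.frame(block = rep(1:2, each = n / 2),
                   probe_id = paste0("p", 1:n),
                   M = rep(c(1, -1), each = n / 2), A = A, usable = TRUE)
  out <- printtip_loess_normalize(sp)
  expect_lt(max(abs(out$M)), 1e-6)
})

test_that("normalization is idempotent on linear-bias data", {
  n <- 150
  A <- seq(6, 14, length.out = n)
  sp <- data.frame(block = 1L, probe_id = paste0("p", 1:n),
                   M = 1 + 0.2 * A, A = A, usable = TRUE)
  once <- printtip_loess_normalize(sp)
  twice <- printtip_loess_normalize(once[setdiff(names(once), "M_raw")])
  expect_lt(max(abs(twice$M - once$M)), 1e-6)
})

test_that("small print-tip groups fall back to median-centering", {
  sp <- data.frame(block = 1L, probe_id = paste0("p", 1:5),
                   M = c(1, 2, 3, 4, 5), A = 8:12, usable = TRUE)
  expect_warning(out <- printtip_loess_normalize(sp), "median")
  expect_equal(stats::median(out$M), 0)
})

test_that("planted per-tip dye bias is recovered by least squares", {
  bias <- cbind(c(0.5, -0.3, 0.1, 0), c(0.05, -0.02, 0.01, 0.03))
  tr <- array_truth(sprintf("g%04d", 1:400),
                    lfc = matrix(0, 400, 1,
                                 dimnames = list(NULL, "S")),
                    n_printtips = 4L, tip_bias = bias, spot_sd = 0)
  des <- data.frame(array_id = "a1", sample = "S_r1", strain = "S",
                    sample_dye = "Cy5", platform = "A")
  sc <- suppressWarnings(simulate_microarray(tr, des))[[1]]
  m_raw <- log2(sc$F_ch1 / sc$F_ch2)
  a <- 0.5 * log2(sc$F_ch1 * sc$F_ch2)
  for (tip in 1:4) {
    sel <- sc$block == tip
    fit <- stats::lm(m_raw[sel] ~ a[sel])
    expect_equal(unname(coef(fit)), unname(bias[tip, ]), tolerance = 1e-6)
  }
})

test_that("zero lfc, zero bias, zero noise gives M = 0 at every spot", {
  tr <- array_truth(sprintf("g%03d", 1:50),
                    lfc = matrix(0, 50, 1, dimnames = list(NULL, "S")),
                    n_printtips = 2L, spot_sd = 0)
  des <- data.frame(array_id = c("a1", "a2"), sample = "S_r1",
                    strain = "S", sample_dye = c("Cy5", "Cy3"),
                    platform = "A")
  scans <- simulate_microarray(tr, des)
  for (sc in scans) {
    out <- ma_transform(sc)
    expect_lt(max(abs(out$M)), 1e-12)
  }
})

test_that("a global dye swap leaves consolidated M unchanged", {
  tr <- default_array_truth(n_genes = 150, n_de = 5, n_de_shared = 2,
                            spot_sd = 0.1, seed = 9)
  des <- dye_swap_design(n_reps = 1L)
  scans <- simulate_microarray(tr, des, seed = 10)
  flip <- function(st) {
    st2 <- st
    st2$F_ch1 <- st$F_ch2; st2$F_ch2 <- st$F_ch1
    st2$sample_ch1 <- st$sample_ch2; st2$sample_ch2 <- st$sample_ch1
    st2$dye_ch1 <- st$dye_ch2; st2$dye_ch2 <- st$dye_ch1
    st2
  }
  orig <- consolidate_dye_swap(lapply(scans[1:2], function(s)
    ma_transform(s)))
  swapped <- consolidate_dye_swap(lapply(scans[1:2], function(s)
    ma_transform(flip(s))))
  expect_equal(orig$M, swapped$M, tolerance = 1e-12)
})

test_that("moderated t reduces to ordinary t and to the pooled limit", {
  set.seed(21)
  M <- matrix(rnorm(50 * 6, 0, 0.3), 50, 6,
              dimnames = list(paste0("g", 1:50), NULL))
  mt0 <- moderated_t(M, prior_df = 0)
  expect_equal(mt0$t, mt0$t_ordinary, tolerance = 1e-12)
  expect_equal(mt0$p, mt0$p_ordinary, tolerance = 1e-12)
  mtInf <- moderated_t(M, prior_df = Inf)
  s0 <- attr(mtInf, "s02")
  expect_equal(mtInf$t, unname(rowMeans(M)) / sqrt(s0 / 6),
               tolerance = 1e-12)
  expect_error(moderated_t(M[, 1, drop = FALSE]), "2 arrays")
})

test_that("moderated t agrees with the limma empirical-Bayes reference", {
  set.seed(22)
  s2_true <- 0.04 * 5 / rchisq(300, 5)
  M <- matrix(rnorm(300 * 6, 0, sqrt(rep(s2_true, 6))), 300, 6,
              dimnames = list(paste0("g", 1:300), NULL))
  mt <- moderated_t(M)
  fit <- limma::eBayes(limma::lmFit(M, design = matrix(1, 6, 1)))
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(mt, "s02"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(mt$p, unname(fit$p.value[, 1]), tolerance = 1e-10)
})

test_that("zero-variance genes get a positive posterior variance", {
  M <- matrix(rnorm(40 * 4, 0, 0.2), 40, 4)
  M[1, ] <- 1.5  # exactly constant
  mt <- moderated_t(M)
  expect_true(all(mt$s2_post > 0))
  expect_true(is.finite(mt$p[1]) && mt$p[1] > 0)
})

test_that("the DE filter applies strict thresholds in at least one strain", {
  res <- data.frame(
    gene_id = c("a", "a", "b", "c", "d"),
    strain = c("S1", "S2", "S1", "S1", "S1"),
    M = c(1.2, 0.1, 2.0, 1.5, 1.01),
    A = c(8, 8, 7.5, 8, 8),
    p = c(0.01, 0.9, 0.01, 0.05, 0.049))
  de <- filter_de(res)
  expect_true(de$flags["a", "S1"])
  expect_false(de$flags["a", "S2"])
  expect_false(de$flags["b", "S1"])   # A = 7.5 exactly: excluded
  expect_false(de$flags["c", "S1"])   # p = 0.05 exactly: excluded
  expect_true(de$flags["d", "S1"])
  expect_setequal(de$union, c("a", "d"))
})

test_that("the DE union recovers exactly the constructed passing genes", {
  set.seed(31)
  n <- 200; k <- 25
  genes <- sprintf("g%03d", 1:n)
  pass <- sample(genes, k)
  res <- do.call(rbind, lapply(c("S1", "S2"), function(s)
    data.frame(gene_id = genes, strain = s,
               M = ifelse(genes %in% pass & s == "S1",
                          2, runif(n, -0.5, 0.5)),
               A = 9, p = ifelse(genes %in% pass & s == "S1", 1e-4,
                                 runif(n, 0.2, 1)))))
  de <- filter_de(res)
  expect_setequal(de$union, pass)
})

test_that("Venn partition equals brute-force enumeration on random flags", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:200)
  flags <- matrix(runif(600) < 0.3, 200, 3,
                  dimnames = list(genes, c("X", "Y", "Z")))
  vp <- venn_partition(flags)
  # oracle: exhaustive loop over genes
  oracle <- c("X" = 0, "Y" = 0, "Z" = 0, "X+Y" = 0, "X+Z" = 0, "Y+Z" = 0,
              "X+Y+Z" = 0)
  comp <- 0
  for (g in genes) {
    key <- paste(c("X", "Y", "Z")[flags[g, ]], collapse = "+")
    if (key == "") comp <- comp + 1 else oracle[key] <- oracle[key] + 1
  }
  expect_equal(as.integer(vp$regions[names(oracle)]),
               as.integer(oracle))
  expect_equal(vp$complement, comp)
  expect_equal(sum(vp$regions) + vp$complement, vp$universe_size)
})

test_that("Venn regions always sum to the universe", {
  flags <- matrix(FALSE, 10, 3,
                  dimnames = list(letters[1:10], c("A", "B", "C")))
  vp <- venn_partition(flags)
  expect_equal(vp$complement, 10)
  expect_equal(vp$union_size, 0)
  flags2 <- flags; rownames(flags2)[1] <- "zz"
  expect_error(venn_partition(flags2, universe = letters[1:10]),
               "outside the universe")
})

test_that("platform intersection is a case-normalized sorted set", {
  expect_equal(intersect_platforms(c("b", "a"), c("a", "b")), c("a", "b"))
  expect_equal(intersect_platforms("a", "b"), character(0))
  expect_error(intersect_platforms(character(0), "a"), "empty")
  set.seed(51)
  la <- sample(sprintf("G%03d", 1:150), 80)
  lb <- sample(sprintf("g%03d", 1:150), 80)
  got <- intersect_platforms(la, lb)
  oracle <- sort(unique(tolower(la)[tolower(la) %in% tolower(lb)]))
  expect_equal(got, oracle)
})

test_that("planted DE genes are recovered with high power and few false calls", {
  tr <- default_array_truth(seed = 3)   # 1000 genes, |lfc| 2, sd 0.3
  des <- dye_swap_design()              # 3 strains x 3 reps x dye swap
  scans <- simulate_microarray(tr, des, seed = 4)
  sbs <- lapply(unique(des$strain), function(s)
    scans[des$array_id[des$strain == s]])
  names(sbs) <- unique(des$strain)
  expr <- expression_results(sbs)
  de <- filter_de(expr)
  planted <- unique(unlist(attr(tr, "de_genes")))
  nulls <- setdiff(tr$gene_ids, planted)
  expect_gte(mean(planted %in% de$union), 0.95)
  expect_lte(mean(nulls %in% de$union), 0.07)
})

test_that("null data give a calibrated type-I error rate", {
  set.seed(61)
  M <- matrix(rnorm(5000 * 6, 0, 0.3), 5000, 6,
              dimnames = list(sprintf("g%04d", 1:5000), NULL))
  mt <- moderated_t(M)
  expect_equal(mean(mt$p < 0.05), 0.05, tolerance = 0.01 / 0.05)
})
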