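# nCounter-style normalization, expression filtering, differential expression,
# overlap arithmetic and counter-regulation pairing.

toy_matrix <- function(scale = c(1, 1, 1, 1), hk_level = 1000) {
  counts <- rbind(
    Actb = hk_level * scale,
    B2m = 0.5 * hk_level * scale,
    "miR-001" = c(200, 220, 400, 410) * scale,
    "miR-002" = c(50, 55, 52, 49) * scale
  )
  colnames(counts) <- c("WT_1", "WT_2", "case_1", "case_2")
  count_matrix(counts, groups = c("WT", "WT", "case", "case"),
               housekeeping = c("Actb", "B2m"), kind = "miRNA_counts")
}

test_that("housekeeping normalization inverts sample scalings exactly", {
  sc <- c(1, 1.5, 0.7, 1)
  nm <- normalize_counts(toy_matrix(scale = sc))
  expect_equal(attr(nm, "scale_factors"), sc / mean(sc),
               tolerance = 1e-9, ignore_attr = TRUE)
  # sample scalings are inverted exactly, up to the common anchor (the
  # across-sample average of housekeeping geometric means)
  base <- toy_matrix()$counts
  expect_equal(nm$counts / mean(sc), base, tolerance = 1e-9)

  # a doubled sample is restored to the structure of the unscaled matrix
  dbl <- normalize_counts(toy_matrix(scale = c(2, 1, 1, 1)))
  expect_equal(dbl$counts / 1.25, base, tolerance = 1e-9)

  # idempotence
  again <- normalize_counts(nm)
  expect_equal(again$counts, nm$counts, tolerance = 1e-12)
  expect_equal(attr(again, "scale_factors"), rep(1, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # housekeeping geometric means equalized by construction
  hk <- nm$counts[nm$housekeeping, ]
  gms <- apply(hk, 2, function(x) exp(mean(log(x))))
  expect_lt(diff(range(gms)), 1e-9 * mean(gms))
})

test_that("zero housekeeping counts are reported by feature and sample", {
  cm <- toy_matrix()
  cm$counts["B2m", "case_1"] <- 0
  expect_error(normalize_counts(cm), "B2m.*case_1")
})

test_that("the expression filter is boundary-inclusive on mean counts", {
  counts <- rbind(a = rep(99.9, 4), b = rep(100, 4), c = rep(250, 4),
                  Actb = rep(1000, 4))
  colnames(counts) <- c("WT_1", "WT_2", "case_1", "case_2")
  cm <- count_matrix(counts, c("WT", "WT", "case", "case"),
                     housekeeping = "Actb")
  flags <- expression_filter(cm)
  expect_equal(unname(flags[c("a", "b", "c")]), c(FALSE, TRUE, TRUE))
  expect_true(all(expression_filter(cm, min_count = 0)))

  # survivor count is non-increasing in min_count
  cm2 <- normalize_counts(simulate_count_matrix(spike_design(seed = 8)))
  surv <- vapply(c(0, 10, 100, 400, 1000),
                 function(mc) sum(expression_filter(cm2, mc)), numeric(1))
  expect_true(all(diff(surv) <= 0))
  # designed expressed features survive the default filter
  expect_equal(sum(expression_filter(cm2)), 166, tolerance = 3)
})

test_that("differential expression handles identical and shifted groups", {
  counts <- rbind(flat = c(300, 300, 300, 300),
                  up = c(100, 100, 200, 200) + c(0.2, -0.2, 0.3, -0.3),
                  Actb = rep(1000, 4))
  colnames(counts) <- c("WT_1", "WT_2", "case_1", "case_2")
  cm <- count_matrix(counts, c("WT", "WT", "case", "case"),
                     housekeeping = "Actb")
  de <- differential_expression(cm, min_count = 50)
  flat <- de[de$feature == "flat", ]
  expect_equal(flat$p_value, 1)
  expect_equal(flat$fold_change, 1, tolerance = 1e-9)
  expect_false(flat$significant)

  up <- de[de$feature == "up", ]
  expect_equal(up$direction, "up")
  expect_equal(up$log2fc, 1, tolerance = 0.02)

  # zero within-group variance with unequal means: p missing, flagged
  counts2 <- rbind(const = c(100, 100, 200, 200), Actb = rep(1000, 4))
  colnames(counts2) <- colnames(counts)
  cm2 <- count_matrix(counts2, c("WT", "WT", "case", "case"),
                      housekeeping = "Actb")
  de2 <- differential_expression(cm2, min_count = 50)
  expect_true(is.na(de2$p_value[de2$feature == "const"]))
  expect_true(de2$flag_zero_var[de2$feature == "const"])
})

test_that("DE p-values are invariant to a global rescaling of all samples", {
  cm <- simulate_count_matrix(spike_design(seed = 14))
  de1 <- differential_expression(normalize_counts(cm))
  cm$counts <- cm$counts * 3
  de2 <- differential_expression(normalize_counts(cm))
  # the +1 pseudo-count breaks exactness at small counts; expressed features
  # (counts >= 100) are invariant to ~1e-3
  expect_equal(de2$p_value, de1$p_value, tolerance = 1e-3)
  expect_identical(de2$significant, de1$significant)
})

test_that("spiked features are recovered with calibrated false positives", {
  sens <- fpr <- numeric(20)
  for (s in seq_len(20)) {
    cm <- simulate_count_matrix(spike_design(seed = 100 + s))
    de <- differential_expression(normalize_counts(cm))
    truth <- attr(cm, "truth")
    sp <- truth$feature[truth$spiked]
    sens[s] <- mean(de$significant[match(sp, de$feature)])
    nulls <- de$expressed & !(de$feature %in% sp)
    fpr[s] <- mean(de$significant[nulls])
  }
  expect_gte(mean(sens), 0.9)
  expect_lt(mean(fpr), 1.5 * 0.05)
})

test_that("set overlaps partition exactly", {
  expect_equal(set_overlap(c("p1", "p2", "p3"), c("p3", "p4")),
               c(a_only = 2, b_only = 1, both = 1))
  expect_equal(set_overlap(c("x"), c("y"))[["both"]], 0)
  # partition sums to the union size
  set.seed(1)
  for (k in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    expect_equal(sum(set_overlap(a, b)), length(union(a, b)))
  }
})

test_that("significant proportions round to integer percents", {
  expect_equal(proportion_significant(74, 1044), 7)
  expect_equal(proportion_significant(147, 1044), 14)
  expect_equal(proportion_significant(0, 1044), 0)
  expect_error(proportion_significant(5, 0), "n_total")
  expect_error(proportion_significant(10, 5), "n_sig")
})

fake_de <- function(features, direction, significant = TRUE) {
  data.frame(feature = features, direction = direction,
             significant = significant, stringsAsFactors = FALSE)
}

test_that("counter-regulation pairing enforces direction and map membership", {
  map <- data.frame(mirna = "m1", protein = "P1")
  res <- counter_regulation_pairs(fake_de("m1", "up"), fake_de("P1", "down"),
                                  map)
  expect_equal(res$n_interactions, 1)
  expect_equal(res$n_mirnas, 1)
  expect_equal(res$n_proteins, 1)

  # protein moving the same way as the miRNA is excluded
  res_up <- counter_regulation_pairs(fake_de("m1", "up"), fake_de("P1", "up"),
                                     map)
  expect_equal(res_up$n_interactions, 0)

  # non-significant members are excluded
  res_ns <- counter_regulation_pairs(fake_de("m1", "up", significant = FALSE),
                                     fake_de("P1", "down"), map)
  expect_equal(res_ns$n_interactions, 0)

  expect_warning(
    counter_regulation_pairs(fake_de("m1", "up"), fake_de("P1", "down"),
                             data.frame(mirna = character(0),
                                        protein = character(0))),
    "empty")
})

test_that("pairing tallies reproduce an engineered 77/31/25 network", {
  mirnas <- sprintf("miR-%02d", 1:31)
  proteins <- sprintf("P%02d", 1:25)
  # each miRNA targets one protein (cycling), plus 46 extra distinct pairs
  pairs <- data.frame(mirna = mirnas,
                      protein = proteins[(seq_len(31) - 1) %% 25 + 1])
  extra <- expand.grid(mirna = mirnas, protein = proteins,
                       stringsAsFactors = FALSE)
  extra <- extra[!paste(extra$mirna, extra$protein) %in%
                   paste(pairs$mirna, pairs$protein), ]
  map <- rbind(pairs, extra[seq_len(46), ])
  # decoys that must not contribute
  map <- rbind(map, data.frame(mirna = "miR-down", protein = "P01"),
               data.frame(mirna = "miR-01", protein = "P-up"))
  mirna_de <- rbind(fake_de(mirnas, "up"), fake_de("miR-down", "down"))
  protein_de <- rbind(fake_de(proteins, "down"), fake_de("P-up", "up"))
  res <- counter_regulation_pairs(mirna_de, protein_de, map)
  expect_equal(res$n_interactions, 77)
  expect_equal(res$n_mirnas, 31)
  expect_equal(res$n_proteins, 25)
})

test_that("volcano coordinates place features on the guide line", {
  de <- data.frame(feature = c("a", "b", "c"),
                   log2fc = c(0, 1, 2),
                   fold_change = c(1, 2, 4),
                   p_value = c(0.05, 0.5, NA),
                   expressed = TRUE,
                   significant = c(TRUE, FALSE, FALSE))
  tab <- volcano_table(de, alpha = 0.05)
  expect_equal(tab$neglog10_p[tab$feature == "a"], -log10(0.05))
  expect_equal(tab$log2fc[tab$feature == "a"], 0)   # fold change 1 at x = 0
  expect_false("c" %in% tab$feature)                # missing p omitted
  expect_equal(attr(tab, "n_omitted"), 1)
})

test_that("count matrices round-trip through TSV with group maps", {
  cm <- simulate_count_matrix(spike_design(n_features = 30, n_expressed = 10,
                                           n_spiked = 3, seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path, housekeeping = cm$housekeeping)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$groups, cm$groups)

  tm <- data.frame(mirna = c("m1", "m2"), protein = c("P1", "P2"))
  tp <- tempfile(fileext = ".tsv")
  utils::write.table(tm, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_target_map(tp), tm)
})
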