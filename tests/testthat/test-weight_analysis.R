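## A weight table with prescribed weights for deterministic checks.
make_weight_table <- function(weights_esc, weights_ipsc,
                              probes = sprintf("cg%08d",
                                               seq_along(weights_esc))) {
  rbind(
    data.frame(class = "ESC", probe_id = probes, weight = weights_esc,
               stringsAsFactors = FALSE),
    data.frame(class = "iPSC", probe_id = probes, weight = weights_ipsc,
               stringsAsFactors = FALSE))
}

test_that("weight extraction mirrors the model's mu vectors", {
  m <- init_model(sprintf("cg%02d", 1:3), r = 1)
  tab <- extract_weight_table(m)
  expect_equal(nrow(tab), 6)  # 2 classes x 3 probes
  expect_true(all(tab$weight == 0))
  set.seed(2)
  m$mu[] <- rnorm(12)
  tab <- extract_weight_table(m)
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$weight[i], m$mu[tab$probe_id[i], tab$class[i]])
  expect_error(extract_weight_table(m, classes = c("ESC", "MEF")), "MEF")
})

test_that("top/bottom selection equals a full-sort oracle on 10^4 entries", {
  set.seed(55)
  n <- 5000  # per class; 10^4 entries combined
  tab <- make_weight_table(rnorm(n), rnorm(n))
  K <- 700
  sel <- select_high_weight(tab, K = K)
  expect_equal(nrow(sel$positive), K)
  expect_equal(nrow(sel$negative), K)
  ## oracle: full sort of the combined entries
  ord <- order(tab$weight, decreasing = TRUE)
  expect_setequal(paste(sel$positive$class, sel$positive$probe_id),
                  paste(tab$class[ord[1:K]], tab$probe_id[ord[1:K]]))
  ordn <- order(tab$weight)
  expect_setequal(paste(sel$negative$class, sel$negative$probe_id),
                  paste(tab$class[ordn[1:K]], tab$probe_id[ordn[1:K]]))
  ## positive weights dominate every unselected weight
  expect_true(min(sel$positive$weight) >=
                max(tab$weight[ord[(K + 1):nrow(tab)]]))
})

test_that("distinct ranks select exactly the expected entries", {
  tab <- make_weight_table(1:10, 11:20)
  sel <- select_high_weight(tab, K = 5)
  expect_setequal(sel$positive$weight, 16:20)
  expect_setequal(sel$negative$weight, 1:5)
  ## K equal to table size returns everything
  sel_all <- select_high_weight(tab, K = 20)
  expect_equal(nrow(sel_all$positive), 20)
  expect_error(select_high_weight(tab, K = 21), "exceeds")
})

test_that("ties at the cutoff resolve deterministically and reproducibly", {
  ## five entries tied exactly at the cutoff value
  tab <- make_weight_table(c(5, 3, 3, 3, 1), c(3, 3, 2, 0, 0))
  sel1 <- select_high_weight(tab, K = 3)
  sel2 <- select_high_weight(tab, K = 3)
  expect_identical(sel1, sel2)
  ## class order breaks the tie: ESC entries precede iPSC at weight 3
  expect_equal(sel1$positive$weight, c(5, 3, 3))
  expect_equal(sel1$positive$class, c("ESC", "ESC", "ESC"))
  expect_equal(sel1$positive$probe_id[2:3],
               sort(sel1$positive$probe_id[2:3]))
})

test_that("per-class counts partition K and feed the fold summary", {
  tab <- make_weight_table(c(9, 8, 1, 1), c(2, 2, 2, 2))
  sel <- select_high_weight(tab, K = 4)
  counts <- per_class_counts(sel)
  expect_equal(sum(counts["positive", ]), 4)
  expect_equal(sum(counts["negative", ]), 4)
  expect_equal(counts["positive", "ESC"], 2)
  expect_equal(counts["positive", "iPSC"], 2)
  ## selection wholly from one class
  tab1 <- make_weight_table(c(5, 4, 3), c(-1, -2, -3))
  sel1 <- select_high_weight(tab1, K = 3)
  expect_equal(unname(per_class_counts(sel1)["positive", ]), c(3, 0))
  ## summary across four identical selections: SEM 0
  summ <- high_weight_count_summary(list(sel, sel, sel, sel))
  expect_true(all(summ$sem == 0))
  expect_equal(summ$mean[summ$class == "ESC" & summ$sign == "positive"], 2)
})

test_that("common sites across folds recover a planted core", {
  set.seed(66)
  core <- sprintf("core%03d", 1:30)
  selections <- lapply(1:4, function(i) {
    ## fold-specific filler around the common core, for both classes/signs
    filler <- function(tag) sprintf("f%d_%s_%02d", i, tag, 1:10)
    list(K = 40, series_id = i,
         positive = data.frame(
           class = rep(c("ESC", "iPSC"), each = 40),
           probe_id = c(c(core, filler("ep")), c(core, filler("ip"))),
           weight = 1, stringsAsFactors = FALSE),
         negative = data.frame(
           class = rep(c("ESC", "iPSC"), each = 40),
           probe_id = c(c(core, filler("en")), c(core, filler("in"))),
           weight = -1, stringsAsFactors = FALSE))
  })
  sig <- common_sites(selections)
  expect_setequal(sig$common$ESC$positive, core)
  expect_setequal(sig$common$iPSC$negative, core)
  expect_setequal(sig$esc_pos_ipsc_neg, core)
  expect_setequal(sig$ipsc_pos_esc_neg, core)
  ## order invariance in the four inputs
  sig2 <- common_sites(selections[c(3, 1, 4, 2)])
  expect_identical(sig2$ipsc_pos_esc_neg, sig$ipsc_pos_esc_neg)
  ## identical selections: common equals the selection itself
  sig3 <- common_sites(selections[c(1, 1, 1, 1)])
  expect_setequal(sig3$common$ESC$positive,
                  selections[[1]]$positive$probe_id[
                    selections[[1]]$positive$class == "ESC"])
  ## disjoint selections: all empty
  disjoint <- lapply(1:4, function(i) {
    s <- selections[[i]]
    s$positive$probe_id <- paste0("only", i, "_", seq_len(80))
    s$negative$probe_id <- paste0("neg", i, "_", seq_len(80))
    s
  })
  sig4 <- common_sites(disjoint)
  expect_length(sig4$common$ESC$positive, 0)
  expect_length(sig4$ipsc_pos_esc_neg, 0)
})

test_that("annotation tallies follow the multi-membership counting rule", {
  ann <- data.frame(
    probe_id = sprintf("cg%02d", 1:20),
    chromosome = rep("8", 20),
    gene_feature_groups = c(rep("TSS200;Body", 5), rep("TSS200", 5),
                            rep("Body", 6), rep("intergenic", 4)),
    cgi_relation = rep(c("Island", "OpenSea"), c(12, 8)),
    maf = NA_real_, stringsAsFactors = FALSE)
  sites <- ann$probe_id
  gf <- annotate_counts(sites, ann, facet = "gene_feature")
  ## hand enumeration: TSS200 = 10, Body = 11, intergenic = 4; total 25
  expect_equal(gf$count[gf$category == "TSS200"], 10)
  expect_equal(gf$count[gf$category == "Body"], 11)
  expect_equal(gf$count[gf$category == "intergenic"], 4)
  expect_equal(sum(gf$count), 25)  # exceeds the 20 sites
  expect_equal(sum(gf$proportion), 1)
  expect_equal(gf$proportion[gf$category == "Body"], 11 / 25)
  cg <- annotate_counts(sites, ann, facet = "cgi_relation")
  expect_equal(cg$count[cg$category == "Island"], 12)
  expect_equal(sum(cg$count), 20)
  ch <- annotate_counts(sites, ann, facet = "chromosome")
  expect_equal(ch$proportion[ch$category == "8"], 1)
  expect_warning(annotate_counts(c(sites, "cgZZ"), ann, "chromosome"),
                 "missing")
})
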