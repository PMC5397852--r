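test_that("pathway size filter counts network-present coding genes", {
  ids <- sprintf("PC%03d", 1:600)
  net <- make_net(data.frame(gene_a = "HUB", gene_b = ids))
  pw <- function(n, extra = 0)
    pathway_gene_set(paste0("P", n), "t",
                     c(ids[seq_len(n)], sprintf("MISSING%02d",
                                                seq_len(extra + 1))[
                                                  seq_len(extra)]))
  kept_sizes <- function(ps) vapply(filter_pathways(ps, net),
                                    function(p) p$size, 1L)
  expect_identical(kept_sizes(list(pw(14), pw(15), pw(500))),
                   c(15L, 500L))
  expect_identical(length(filter_pathways(list(pw(501)), net)), 0L)
  # genes absent from the network do not count toward the size
  expect_identical(kept_sizes(list(pw(15, extra = 40))), 15L)
  expect_identical(length(filter_pathways(list(
    pathway_gene_set("PX", "t", "NOT_IN_NET")), net)), 0L)
})

test_that("running sum reproduces the hand-computed toy example", {
  sc <- toy_scores()
  p <- pathway_gene_set("P", "toy", c("g1", "g3"))
  out <- enrichment_score(sc, p)
  expect_equal(out$running_sum,
               c(0.625, 0.625 - 1/3, 2/3, 1/3, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$es, 2/3, tolerance = 1e-12)
  expect_identical(out$peak_index, 3L)
  expect_identical(core_genes(sc, p, out$peak_index), c("g1", "g3"))
})

test_that("both running fractions terminate at unity", {
  set.seed(41)
  for (k in 1:10) {
    n <- sample(20:100, 1)
    sc <- stats::setNames(sort(runif(n), decreasing = TRUE),
                          sprintf("G%03d", sample(n)))
    p <- pathway_gene_set("P", "t", sample(names(sc), sample(3:10, 1)))
    out <- enrichment_score(sc, p)
    expect_equal(out$running_sum[n], 0, tolerance = 1e-12)  # 1 - 1
    expect_true(all(out$running_sum <= 1 + 1e-12))
  }
})

test_that("ES is scale invariant and 1 exactly on prefix placements", {
  set.seed(42)
  sc <- stats::setNames(sort(rexp(50), decreasing = TRUE),
                        sprintf("G%02d", 1:50))
  p <- pathway_gene_set("P", "t", sample(names(sc), 8))
  e1 <- enrichment_score(sc, p)$es
  e2 <- enrichment_score(sc * 137.5, p)$es
  expect_equal(e1, e2, tolerance = 1e-12)

  prefix <- pathway_gene_set("Q", "t", names(sc)[1:8])
  expect_equal(enrichment_score(sc, prefix)$es, 1, tolerance = 1e-12)
  # and conversely: a non-prefix pathway scores strictly below 1
  nonpre <- pathway_gene_set("R", "t", names(sc)[c(1:7, 20)])
  expect_lt(enrichment_score(sc, nonpre)$es, 1)
})

test_that("weight exponent zero reduces to the unweighted KS statistic", {
  set.seed(43)
  for (k in 1:50) {
    n <- sample(30:200, 1)
    sc <- stats::setNames(sort(runif(n), decreasing = TRUE),
                          sprintf("G%03d", sample(n)))
    p <- pathway_gene_set("P", "t", sample(names(sc), sample(5:15, 1)))
    expect_equal(enrichment_score(sc, p, weight_exponent = 0)$es,
                 ks_unweighted_oracle(names(sc), p$genes),
                 tolerance = 1e-12)
  }
})

test_that("bottom-clustered pathways yield ES 0 and an empty core", {
  sc <- stats::setNames(seq(1, 0.1, length.out = 10),
                        sprintf("G%02d", 1:10))
  p <- pathway_gene_set("P", "t", names(sc)[9:10])
  out <- enrichment_score(sc, p)
  expect_equal(out$es, 0, tolerance = 1e-12)
  expect_identical(out$peak_index, 0L)
  expect_identical(core_genes(sc, p, out$peak_index), character(0))
})

test_that("unreachable and degenerate pathways raise errors", {
  sc <- stats::setNames(c(0.5, 0.3, 0, 0), sprintf("G%d", 1:4))
  expect_error(enrichment_score(sc, pathway_gene_set("P", "t",
                                                     c("G3", "G4"))),
               "unreachable")
  expect_error(enrichment_score(sc, pathway_gene_set("P", "t", "ZZZ")),
               "no genes in the ranked list")
  expect_error(enrichment_score(sc, pathway_gene_set("P", "t",
                                                     names(sc))),
               "entire ranked list")
})

test_that("permutation p-values follow the strict-greater count", {
  # nulls {0.2, 0.5, 0.7, 0.9} vs observed 0.6 -> 2/4
  expect_equal(sum(c(0.2, 0.5, 0.7, 0.9) > 0.6) / 4, 0.5)
  set.seed(44)
  sim <- generate_cnc(synthetic_spec(n_coding = 270, n_lnc = 30,
                                     planted_pathway_size = 20,
                                     n_decoy_pathways = 3, rng_seed = 44))
  net <- restrict_to_components(sim$network)$network
  paths <- filter_pathways(c(list(sim$planted_pathway), sim$decoys), net,
                           min_size = 5)
  prop <- rank_coding_genes(rwr(net, sim$seeds), net)
  obs <- vapply(paths, function(p) enrichment_score(prop, p)$es, 0)
  names(obs) <- vapply(paths, function(p) p$pathway_id, "")
  perm <- permutation_test(net, length(sim$seeds), paths,
                           n_permutations = 25, rng_seed = 45,
                           observed_es = obs)
  nulls <- attr(perm, "es_null")
  for (k in seq_along(paths)) {
    expect_equal(perm$p_value[k],
                 sum(nulls[, k] > obs[[perm$pathway_id[k]]]) / 25)
  }
  # observed above every null -> p exactly 0; pseudocount variant shifts it
  expect_equal(permutation_test(net, length(sim$seeds), paths[1],
                                n_permutations = 10, rng_seed = 45,
                                observed_es = c(PLANTED = 2))$p_value, 0)
  expect_equal(permutation_test(net, length(sim$seeds), paths[1],
                                n_permutations = 10, rng_seed = 45,
                                observed_es = c(PLANTED = 2),
                                pseudocount = TRUE)$p_value, 1 / 11)
  expect_error(permutation_test(net, 1e4, paths, n_permutations = 1,
                                observed_es = obs),
               "fewer lncRNA")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone after sorting by raw p, never below raw p
  set.seed(46)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("fold-change flags use a strict threshold and pseudocounts", {
  case <- c(A = 4, B = 2, C = 0.4, D = 0, E = 3)
  ctrl <- c(A = 1, B = 1, C = 1, D = 1, E = 0)
  out <- flag_differential_core_genes(c("A", "B", "C", "D", "E", "MISS"),
                                      case, ctrl)
  expect_identical(stats::setNames(out$flagged, out$gene)[c("A", "B", "C")],
                   c(A = TRUE, B = FALSE, C = TRUE))
  expect_true(all(out$pseudocount_used[out$gene %in% c("D", "E")]))
  expect_identical(out$status[out$gene == "MISS"], "not_evaluable")
  expect_equal(attr(out, "fraction_flagged"),
               mean(out$flagged[out$status == "ok"]))
})
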