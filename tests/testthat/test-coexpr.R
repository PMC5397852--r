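make_ds <- function(x, biotype = rep("coding", nrow(x)),
                    id = "ds") {
  expression_dataset(id, x, biotype)
}

test_that("gene filter applies the mean and variance rules with kept ties", {
  set.seed(1)
  base <- matrix(rnorm(3 * 10, sd = 2), nrow = 3)
  x <- abs(base) + 0.01
  x <- x / rowMeans(x) * c(0.5, 2, 3)  # means 0.5, 2, 3; variance untouched
  rownames(x) <- c("low", "mid", "high")
  out <- filter_genes(make_ds(x))
  expect_identical(rownames(out$fpkm), c("mid", "high"))

  # identical variances: everyone ties at the cutoff, everyone stays
  x2 <- matrix(rep(c(9, 11), each = 4), nrow = 4, ncol = 8,
               dimnames = list(paste0("g", 1:4), NULL))
  out2 <- filter_genes(make_ds(x2))
  expect_identical(nrow(out2$fpkm), 4L)

  # 4 genes, variances strictly ordered: bottom quartile dropped
  x3 <- t(sapply(1:4, function(k) 10 + k * scale(rnorm(12))[, 1]))
  rownames(x3) <- paste0("v", 1:4)
  x3 <- abs(x3) + 5
  v <- apply(x3, 1, var)
  out3 <- filter_genes(make_ds(x3))
  expect_identical(rownames(out3$fpkm), rownames(x3)[v > min(v)])

  # nothing survives -> explicit error
  xfail <- matrix(0.1, nrow = 2, ncol = 6,
                  dimnames = list(c("a", "b"), NULL))
  expect_error(filter_genes(make_ds(xfail)), "no genes pass")
})

test_that("Fisher z matches atanh, is odd and strictly increasing", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(r), atanh(r), tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "degenerate")
  expect_error(fisher_z(-1.2), "degenerate")
})

test_that("a planted high-correlation pair is flagged with its sign", {
  set.seed(7)
  n <- 200; ns <- 20
  x <- matrix(rlnorm(n * ns, meanlog = 2), nrow = n,
              dimnames = list(sprintf("G%03d", 1:n), NULL))
  base <- rnorm(ns)
  x["G001", ] <- exp(2 + base)
  x["G002", ] <- exp(2 + 0.99 * base + sqrt(1 - 0.99^2) * rnorm(ns))
  out <- dataset_coexpression(make_ds(x))
  hit <- out[out$gene_a == "G001" & out$gene_b == "G002", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$sign, 1L)
  expect_gt(hit$r, 0.9)
  expect_lt(hit$p_adj, 0.01)
})

test_that("independent genes produce (almost) no flagged pairs", {
  set.seed(8)
  x <- matrix(rlnorm(500 * 20, meanlog = 2), nrow = 500,
              dimnames = list(sprintf("G%03d", 1:500), NULL))
  out <- dataset_coexpression(make_ds(x))
  expect_lt(nrow(out), 0.001 * choose(500, 2))
})

test_that("the rank rule is enforced from both endpoints", {
  # exact geometry: orthonormal centered directions give HUB ten partners
  # at r = 0.999 while cor(AAA, HUB) = 0.95 and cor(AAA, clone) = 0.94905,
  # so AAA ranks HUB first but HUB ranks AAA 11th
  set.seed(9)
  ns <- 20
  q <- qr.Q(qr(scale(matrix(rnorm(ns * 13), ns, 13), scale = FALSE)))
  u <- q[, 1]
  hub <- 10 + 5 * u
  clones <- t(sapply(1:10, function(k)
    10 + 5 * (0.999 * u + sqrt(1 - 0.999^2) * q[, k + 1])))
  a <- 10 + 5 * (0.95 * u + sqrt(1 - 0.95^2) * q[, 12])
  x <- matrix(rlnorm(30 * ns, meanlog = 2), nrow = 30,
              dimnames = list(sprintf("BG%02d", 1:30), NULL))
  x <- rbind(x, HUB = hub, clones, AAA = a)
  rownames(x)[32:41] <- sprintf("CL%02d", 1:10)
  # alpha above the p-value cap disables the significance gate so the
  # assertion isolates the rank rule
  both <- dataset_coexpression(make_ds(x), alpha = 2)
  either <- dataset_coexpression(make_ds(x), alpha = 2,
                                 endpoint_rule = "either")
  pair_in <- function(df) any(df$gene_a == "AAA" & df$gene_b == "HUB")
  # AAA's best partner is HUB, but HUB ranks its clones above AAA
  expect_false(pair_in(both))
  expect_true(pair_in(either))
})

test_that("flagged pairs are invariant to gene order in the matrix", {
  set.seed(10)
  x <- matrix(rlnorm(50 * 12, meanlog = 2), nrow = 50,
              dimnames = list(sprintf("G%02d", 1:50), NULL))
  base <- rnorm(12)
  x["G01", ] <- exp(base); x["G27", ] <- exp(base + 0.05 * rnorm(12))
  out1 <- dataset_coexpression(make_ds(x), alpha = 0.05)
  perm <- sample(nrow(x))
  out2 <- dataset_coexpression(make_ds(x[perm, ]), alpha = 0.05)
  key <- function(df) sort(paste(df$gene_a, df$gene_b, df$sign))
  expect_identical(key(out1), key(out2))
})

test_that("constant genes are skipped with a warning, tiny N errors", {
  x <- matrix(rlnorm(5 * 8, meanlog = 2), nrow = 5,
              dimnames = list(paste0("g", 1:5), NULL))
  x["g3", ] <- 2
  expect_warning(dataset_coexpression(make_ds(x)), "constant")
  ds_small <- structure(list(dataset_id = "s", fpkm = x[, 1:3],
                             biotype = stats::setNames(rep("coding", 5),
                                                       rownames(x)),
                             n_samples = 3L),
                        class = "expression_dataset")
  expect_error(dataset_coexpression(ds_small), "N <= 3")
})

test_that("consensus requires same-direction support in enough datasets", {
  pair <- function(sign) data.frame(gene_a = "A", gene_b = "B",
                                    sign = sign, stringsAsFactors = FALSE)
  # positive in 3 of 5 -> kept with support 3
  sets <- list(pair(1L), pair(1L), pair(1L), pair(-1L),
               data.frame(gene_a = character(), gene_b = character(),
                          sign = integer(), stringsAsFactors = FALSE))
  out <- consensus_edges(sets)
  expect_identical(out$sign, 1L)
  expect_identical(out$support, 3L)

  # 2 positive + 1 negative -> no direction reaches 3 -> dropped
  out2 <- consensus_edges(list(pair(1L), pair(1L), pair(-1L)))
  expect_identical(nrow(out2), 0L)

  # empty input sets -> empty output
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      sign = integer(), stringsAsFactors = FALSE)
  expect_identical(nrow(consensus_edges(list(empty, empty, empty))), 0L)
})

test_that("raising min_support never adds consensus edges", {
  set.seed(11)
  sets <- lapply(1:6, function(d) {
    k <- sample(3:8, 1)
    data.frame(gene_a = sample(LETTERS[1:6], k, TRUE),
               gene_b = sample(LETTERS[7:12], k, TRUE),
               sign = sample(c(-1L, 1L), k, TRUE),
               stringsAsFactors = FALSE)
  })
  prev <- NULL
  for (ms in 1:6) {
    cur <- consensus_edges(sets, min_support = ms)
    keys <- paste(cur$gene_a, cur$gene_b, cur$sign)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})
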