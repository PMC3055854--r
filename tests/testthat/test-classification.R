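test_that("10% classification takes the extremes and the centered middle", {
  g10 <- data.frame(gene_id = sprintf("g%02d", 1:10), ka = (1:10) / 100)
  cls <- classifyByKa(g10)
  expect_equal(sum(cls$class == "slow"), 1)
  expect_equal(sum(cls$class == "intermediate"), 1)
  expect_equal(sum(cls$class == "fast"), 1)
  expect_equal(cls$gene_id[cls$class == "slow"], "g01")
  expect_equal(cls$gene_id[cls$class == "fast"], "g10")

  # 20 genes, k = 2, intermediate window = ranks 10-11
  g20 <- data.frame(gene_id = sprintf("g%02d", 1:20), ka = (1:20) / 100)
  c20 <- classifyByKa(g20, 0.10)
  expect_equal(sum(c20$class == "slow"), 2)
  expect_equal(sum(c20$class == "intermediate"), 2)
  expect_equal(sum(c20$class == "fast"), 2)
  expect_equal(c20$rank[c20$class == "intermediate"], c(10L, 11L))
})

test_that("NA Ka sorts to the slow end via the NA -> 0 rule", {
  g <- data.frame(gene_id = sprintf("g%02d", 1:12),
                  ka = c(NA, (2:12) / 100))
  cls <- classifyByKa(g)
  expect_equal(cls$rank[cls$gene_id == "g01"], 1L)
  expect_equal(as.character(cls$class[cls$gene_id == "g01"]), "slow")
  expect_equal(cls$ka[cls$gene_id == "g01"], 0)
})

test_that("classification is invariant to input order and validates input", {
  set.seed(3)
  g <- data.frame(gene_id = sprintf("g%02d", 1:20),
                  ka = runif(20))
  c1 <- classifyByKa(g)
  c2 <- classifyByKa(g[sample(20), ])
  expect_equal(c1, c2)

  expect_error(classifyByKa(data.frame(gene_id = c("a", "a"),
                                       ka = c(1, 2))), "duplicate")
  expect_error(classifyByKa(data.frame(gene_id = letters[1:5],
                                       ka = 1:5 / 10)), "too few")
})

test_that("class sizes are exactly k whenever n >= 3k", {
  set.seed(4)
  for (n in c(10, 23, 30, 57, 100)) {
    g <- data.frame(gene_id = sprintf("g%03d", 1:n), ka = runif(n))
    cls <- classifyByKa(g, 0.10)
    k <- floor(0.10 * n)
    counts <- table(cls$class)[c("slow", "intermediate", "fast")]
    expect_equal(unname(as.integer(counts)), rep(as.integer(k), 3),
                 info = n)
  }
})

test_that("shared-class counts intersect per-species class sets", {
  mk <- function(sp, fast, slow, rest) {
    data.frame(species_id = sp,
               gene_id = c(fast, slow, rest),
               ka = seq_along(c(fast, slow, rest)),
               rank = seq_along(c(fast, slow, rest)),
               class = c(rep("fast", length(fast)),
                         rep("slow", length(slow)),
                         rep("unclassified", length(rest))))
  }
  tabs <- list(
    A = mk("A", c("a", "b", "c"), "z", "q"),
    B = mk("B", c("b", "c", "d"), "z", "q"),
    C = mk("C", c("b", "e"), "y", "q"))
  expect_equal(sharedClassCounts(tabs, "fast"), 1)
  expect_equal(sharedClassCounts(tabs, "fast", c("A", "B")), 2)
  expect_equal(sharedClassCounts(tabs, "slow", c("A", "B")), 1)
  expect_equal(sharedClassCounts(tabs, "slow"), 0)
  expect_error(sharedClassCounts(tabs, "fast", c("A", "X")), "unknown")
  # monotone non-increasing as species are added
  expect_gte(sharedClassCounts(tabs, "fast", c("A", "B")),
             sharedClassCounts(tabs, "fast", c("A", "B", "C")))
})

test_that("species network coefficients normalize by shared genes", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:20)
  mk <- function(sp, perm) {
    ka <- runif(20)
    classifyByKa(data.frame(gene_id = genes[perm], ka = ka),
                 speciesId = sp)
  }
  tabs <- list(A = mk("A", 1:20), B = mk("B", 1:20), C = mk("C", 1:20))
  edges <- buildSpeciesNetwork(tabs)
  expect_true(all(edges$coefficient >= 0 & edges$coefficient <= 1))
  expect_setequal(unique(edges$class), c("fast", "slow", "both"))
  # both = fast + slow per pair
  for (j in which(edges$class == "both")) {
    sel <- edges$species_a == edges$species_a[j] &
      edges$species_b == edges$species_b[j]
    expect_equal(edges$coefficient[j],
                 sum(edges$coefficient[sel & edges$class != "both"]),
                 tolerance = 1e-12)
  }
  # identical class tables: fast coefficient = share of fast among shared
  tabsSame <- list(A = tabs$A, B = tabs$A, C = tabs$A)
  eS <- buildSpeciesNetwork(tabsSame)
  expect_equal(eS$coefficient[eS$class == "fast"][1], 2 / 20)

  expect_error(buildSpeciesNetwork(tabs[1:2]), "at least 3")
})

test_that("per-species retention keeps at most two edges per node/class", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:30)
  tabs <- lapply(setNames(nm = LETTERS[1:5]), function(sp)
    classifyByKa(data.frame(gene_id = genes, ka = runif(30)),
                 speciesId = sp))
  edges <- buildSpeciesNetwork(tabs, retention = "per_species")
  for (cl in c("fast", "slow", "both")) {
    sub <- edges[edges$class == cl & edges$retained, ]
    # each node can force at most 2 retentions
    expect_lte(nrow(sub), 2 * 5)
    expect_gte(nrow(sub), 2)
    for (j in seq_len(nrow(sub))) {
      # a retained edge ranks within the top two (ties allowed) of at
      # least one of its endpoints
      ok <- any(vapply(c(sub$species_a[j], sub$species_b[j]), function(s) {
        inc <- edges$class == cl & (edges$species_a == s |
                                      edges$species_b == s)
        cf <- sort(edges$coefficient[inc], decreasing = TRUE)
        sub$coefficient[j] >= cf[min(2, length(cf))]
      }, logical(1)))
      expect_true(ok)
    }
  }
  # per-pair retention keeps exactly one class edge (plus its both row at
  # most) per species pair
  ep <- buildSpeciesNetwork(tabs, retention = "per_pair")
  for (j in which(!duplicated(paste(ep$species_a, ep$species_b)))) {
    sel <- ep$species_a == ep$species_a[j] & ep$species_b == ep$species_b[j]
    expect_equal(sum(ep$retained[sel & ep$class != "both"]), 1)
  }
})
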