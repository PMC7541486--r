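mk_terms <- function(...) {
  # build a term_enrichment data frame from (subtype, term, genes, padj) rows
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(subtype = r[[1]], term = r[[2]], namespace = "BP",
               overlap = length(r[[3]]), p = r[[4]] %||% 0.01,
               padj = r[[4]] %||% 0.01, stringsAsFactors = FALSE)))
  out$genes <- I(lapply(rows, function(r) r[[3]]))
  class(out) <- c("term_enrichment", class(out))
  out
}

test_that("over-representation p matches the hypergeometric tail sum", {
  universe <- sprintf("g%03d", 1:100)
  de <- list(S = universe[1:10])
  sets <- list(T1 = universe[c(1:5, 50:54)])   # overlap 5 of size 10
  res <- go_overrepresentation(de, sets, universe, alpha = 1)
  # oracle: enumerate the tail P(X >= 5)
  tail_p <- sum(vapply(5:10, function(x)
    choose(10, x) * choose(90, 10 - x) / choose(100, 10), numeric(1)))
  expect_equal(res$p[1], tail_p, tolerance = 1e-12)
  # extremal: a term equal to the DE set beats every other term
  sets2 <- c(sets, list(T0 = universe[1:10], T2 = universe[40:60]))
  res2 <- go_overrepresentation(de, sets2, universe, alpha = 1)
  expect_equal(res2$term[which.min(res2$p)], "T0")
  # enriched gene set is DE intersect term
  expect_setequal(res2$genes[[which(res2$term == "T0")]], universe[1:10])
})

test_that("null DE draws retain about the nominal fraction of terms", {
  universe <- sprintf("g%03d", 1:200)
  set.seed(5)
  sets <- lapply(1:20, function(i) sample(universe, 20))
  names(sets) <- paste0("T", 1:20)
  retained <- vapply(1:200, function(s) {
    set.seed(s)
    de <- list(S = sample(universe, 25))
    nrow(go_overrepresentation(de, sets, universe, alpha = 0.05))
  }, numeric(1))
  # BH at 0.05 over 20 terms: expected retained well under 2x nominal
  expect_lte(mean(retained) / 20, 2 * 0.05)
})

test_that("autopsy filter removes terms with >20% autopsy genes", {
  tr <- mk_terms(list("S", "T1", c("a", "b", "c", "d", "e"), 0.01),
                 list("S", "T2", c("a", "b", "c", "d", "x"), 0.01))
  # T1 has 1/5 = 20% autopsy genes (kept, not >20%); T2 has 2/5 (removed)
  out <- autopsy_filter(tr, c("a", "x", "zz"))
  expect_identical(out$term, "T1")
  expect_identical(autopsy_filter(tr, character(0))$term, c("T1", "T2"))
})

test_that("within-subtype term clustering follows Jaccard distances", {
  tr <- mk_terms(list("S", "A", c("g1", "g2", "g3"), 0.01),
                 list("S", "B", c("g1", "g2", "g3"), 0.01),   # identical to A
                 list("S", "C", c("g9", "g8"), 0.01))          # disjoint
  cl <- cluster_terms_within_subtype(tr)
  expect_equal(cl$within_cluster[1], cl$within_cluster[2])
  expect_false(cl$within_cluster[3] == cl$within_cluster[1])
  # hand-traced agglomeration for five sets under complete linkage, h=0.66:
  # J(a,b)=2/4=0.5 -> d=.5; c={g1,g4,g5}: d(a,c)=1-1/5=.8; e disjoint
  sets <- list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4"),
               c = c("g1", "g4", "g5"), d = c("g1", "g2", "g3", "g4"),
               e = c("x1", "x2"))
  tr5 <- do.call(mk_terms, lapply(names(sets), function(n)
    list("S", n, sets[[n]], 0.01)))
  cl5 <- cluster_terms_within_subtype(tr5)
  got <- setNames(cl5$within_cluster, cl5$term)
  d <- 1 - outer(names(sets), names(sets), Vectorize(function(i, j)
    length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))))
  dimnames(d) <- list(names(sets), names(sets))
  oracle <- stats::cutree(stats::hclust(stats::as.dist(d), "complete"),
                          h = 0.66)
  expect_equal(unname(got[names(oracle)] == got["a"]),
               unname(oracle == oracle["a"]))
})

test_that("cross-subtype collapse reproduces the fraction distance", {
  # three terms over five subtypes with known co-clustering pattern
  rows <- list()
  pat <- list(S1 = c(A = 1, B = 1, C = 2),  # A,B together
              S2 = c(A = 1, B = 2, C = 2),  # A,B apart
              S3 = c(A = 1, B = 1),          # A,B together (C absent)
              S4 = c(A = 1, B = 1, C = 1),
              S5 = c(B = 1, C = 2))
  for (s in names(pat)) for (tm in names(pat[[s]]))
    rows[[length(rows) + 1]] <- list(s, tm, paste0(s, tm, 1:3), 0.01)
  tr <- do.call(mk_terms, rows)
  tr$within_cluster <- unlist(lapply(names(pat), function(s)
    unname(pat[[s]])))
  pc <- collapse_terms_across_subtypes(tr)
  # f(A,B): shared in S1..S4, apart only in S2 -> 1/4
  expect_equal(pc$distance["A", "B"], 0.25)
  # f(A,C): shared S1, S2, S4; apart in S1 and S2 -> 2/3
  expect_equal(pc$distance["A", "C"], 2 / 3, tolerance = 1e-12)
  # f(B,C): shared S1, S2, S4, S5; apart in S1 and S5 -> 1/2
  expect_equal(pc$distance["B", "C"], 0.5)
  # symmetry and range over all pairs
  expect_true(all(pc$distance >= 0 & pc$distance <= 1))
  expect_identical(pc$distance, t(pc$distance))
  # average-linkage merge: d(A,B)=.25 < .66 merges; C stays apart since
  # avg(d(C,A), d(C,B)) = (0.5 + 2/3)/2 = 0.58 < 0.66 -> all three merge
  expect_equal(length(unique(pc$membership)), 1L)
})

test_that("terms never co-enriched stay apart and naming uses min mean log p", {
  tr <- mk_terms(list("S1", "A", c("g1", "g2"), 1e-6),
                 list("S2", "B", c("g3", "g4"), 0.04))
  tr$within_cluster <- c(1L, 1L)
  pc <- collapse_terms_across_subtypes(tr)
  expect_equal(pc$distance["A", "B"], 1)
  expect_equal(length(unique(pc$membership)), 2L)
  # the more significant member names its cluster
  expect_true("A" %in% pc$representative)
  # collapsing never increases the number of entities
  expect_lte(length(unique(pc$membership)), length(unique(tr$term)))
})

test_that("heatmap rows are capped, L1-normalized and grouped", {
  rows <- list(list("S1", "A", "g1", 1e-15),  # -log10 p = 15 -> capped at 10
               list("S2", "B", "g2", 1e-3))
  tr <- do.call(mk_terms, rows)
  tr$within_cluster <- c(1L, 1L)
  pc <- collapse_terms_across_subtypes(tr)
  hm <- heatmap_groups(pc, tr, min_group = 1)
  expect_equal(max(hm$matrix), 10)
  # a cluster enriched in one subtype is a unit basis row
  expect_equal(sort(unname(hm$normalized[1, ])), c(0, 1))
  expect_true(all(abs(rowSums(hm$normalized) - 1) < 1e-12))
  # identical rows form one group of full size
  tr6 <- do.call(mk_terms, lapply(1:6, function(i)
    list("S1", paste0("T", i), paste0("q", i), 0.01)))
  tr6$within_cluster <- seq_len(6)
  pc6 <- collapse_terms_across_subtypes(tr6)
  hm6 <- heatmap_groups(pc6, tr6, min_group = 5)
  expect_equal(length(hm6$retained), 1L)
  expect_equal(sum(hm6$groups == hm6$retained), 6L)
})

test_that("pair embedding is deterministic and respects input similarity", {
  skip_if_not_installed("uwot")
  set.seed(8)
  rows <- list()
  # two planted blocks of similar gene sets
  for (i in 1:8) rows[[i]] <- list(paste0("S", i), "A",
                                   c("g1", "g2", "g3", paste0("x", i)), 0.01)
  for (i in 1:8) rows[[8 + i]] <- list(paste0("S", i), "B",
                                       c("h1", "h2", "h3", paste0("y", i)),
                                       0.01)
  tr <- do.call(mk_terms, rows)
  tr$within_cluster <- 1L
  pc <- list(membership = c(A = 1L, B = 2L),
             representative = c(`1` = "A", `2` = "B"))
  class(pc) <- "pathway_cluster"
  e1 <- pair_embedding(tr, pc, k = 5, seed = 3)
  e2 <- pair_embedding(tr, pc, k = 5, seed = 3)
  expect_identical(e1, e2)
  # block structure: mean within-block distance < between-block distance
  d <- as.matrix(stats::dist(e1[, c("x", "y")]))
  same <- outer(e1$cluster, e1$cluster, "==")
  expect_lt(mean(d[same & upper.tri(d)]), mean(d[!same & upper.tri(d)]))
})

test_that("subtype-similarity weights reproduce the inverse-sum definition", {
  # hand computation: subtype K has pathways P1={g1,g2}, P2={g1,g2,g3};
  # JS(P1,P1)=1, JS(P1,P2)=2/3 -> w(K,P1)=1/(1+2/3)=0.6
  tr <- mk_terms(list("K", "P1", c("g1", "g2"), 0.01),
                 list("K", "P2", c("g1", "g2", "g3"), 0.01),
                 list("L", "P1", c("g1", "g2"), 0.01),
                 list("M", "P3", c("z1"), 0.01),
                 list("M", "P4", c("z9"), 0.01))
  ss <- subtype_similarity(tr, h = 1.2)
  expect_equal(ss$weights["K", "P1"], 1 / (1 + 2 / 3), tolerance = 1e-12)
  expect_equal(ss$weights["K", "P2"], 1 / (1 + 2 / 3), tolerance = 1e-12)
  # a single pathway of self-similarity 1 gets weight 1
  expect_equal(ss$weights["L", "P1"], 1)
  # weighted Jaccard by hand: K vs L share P1: min/max sums
  wk <- ss$weights["K", ]; wl <- ss$weights["L", ]
  expect_equal(ss$similarity["K", "L"],
               sum(pmin(wk, wl)) / sum(pmax(wk, wl)), tolerance = 1e-12)
  # diagonal 1; disjoint profiles similarity 0
  expect_true(all(diag(ss$similarity) == 1))
  expect_equal(ss$similarity["K", "M"], 0)
})

test_that("subtype similarity is invariant to pathway relabeling and scaling", {
  tr <- mk_terms(list("K", "P1", c("g1", "g2"), 0.01),
                 list("K", "P2", c("g2", "g3"), 0.01),
                 list("L", "P1", c("g1", "g2"), 0.01),
                 list("L", "P2", c("g9"), 0.01))
  s1 <- subtype_similarity(tr)
  tr2 <- tr
  tr2$term <- c(P1 = "Q7", P2 = "Q2")[tr2$term]
  s2 <- subtype_similarity(tr2)
  expect_equal(s1$similarity, s2$similarity, ignore_attr = TRUE)
  # identical profiles -> similarity 1 and co-clustering
  tr3 <- mk_terms(list("K", "P1", c("g1"), 0.01),
                  list("L", "P1", c("g1"), 0.01))
  s3 <- subtype_similarity(tr3)
  expect_equal(s3$similarity["K", "L"], 1)
  expect_equal(s3$assignment[["K"]], s3$assignment[["L"]])
})
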