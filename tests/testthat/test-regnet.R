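write_net <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("network parser handles synonyms, dedup and rejects unknown effects", {
  p <- write_net(c("regulator\tsigma\tgene\teffect",
                   "CRP-cAMP\tRpoD\tptsG\t+",
                   "CRP-cAMP\tRpoD\tptsG\tactivation",
                   "ArcA\tRpoD\tsdhC\t-",
                   "FlhDC\tRpoF\tflgA\tACT"))
  net <- read_network(p)
  expect_equal(nrow(net), 3L)  # the two ptsG rows collapse
  expect_setequal(net$mode[net$gene == "ptsG"], "activation")
  expect_equal(net$mode[net$gene == "sdhC"], "repression")
  # comma dialect, no header
  p2 <- write_net("CRP-cAMP,RpoD,ptsG,+")
  expect_equal(read_network(p2)$mode, "activation")
  p3 <- write_net(c("CRP-cAMP\tRpoD\tptsG\t+", "FNR\tRpoD\tnarG\t?"))
  expect_error(read_network(p3), "line 2.*\\?")
  expect_error(read_network(write_net(character(0))), "empty")
  expect_error(read_network(tempfile()), "not found")
})

test_that("signatures match brute-force grouping and respect the universe", {
  net <- data.frame(
    tf = c("CRP-cAMP", "ArcA", "CRP-cAMP", "FNR"),
    sf = c("RpoD", "RpoD", "RpoD", "RpoD"),
    gene = c("g1", "g1", "g2", "outside"),
    mode = c("activation", "repression", "activation", "activation"),
    stringsAsFactors = FALSE)
  expect_message(sig <- build_signatures(net, c("g1", "g2", "g3")), "1 interaction")
  expect_equal(sig$g1, sort(c("CRP-cAMP/RpoD:activation", "ArcA/RpoD:repression")))
  expect_equal(sig$g2, "CRP-cAMP/RpoD:activation")
  expect_length(sig$g3, 0L)
  # brute-force grouping oracle on a random toy table
  set.seed(21)
  genes <- sprintf("g%d", 1:12)
  toy <- data.frame(tf = sample(LETTERS[1:4], 40, TRUE), sf = "RpoD",
                    gene = sample(genes, 40, TRUE),
                    mode = sample(c("activation", "repression"), 40, TRUE),
                    stringsAsFactors = FALSE)
  sig2 <- build_signatures(toy, genes)
  for (g in genes) {
    rows <- toy[toy$gene == g, ]
    expect_equal(sig2[[g]],
                 sort(unique(paste0(rows$tf, "/", rows$sf, ":", rows$mode))))
  }
})

test_that("combination index is the exact inverse of signatures", {
  set.seed(5)
  for (rep in 1:5) {
    genes <- sprintf("g%d", 1:15)
    toy <- data.frame(tf = sample(LETTERS[1:5], 50, TRUE), sf = "RpoD",
                      gene = sample(genes, 50, TRUE),
                      mode = sample(c("activation", "repression"), 50, TRUE),
                      stringsAsFactors = FALSE)
    sig <- build_signatures(toy, genes)
    idx <- build_combination_index(sig)
    # round trip: re-derive signatures from the index
    back <- lapply(genes, function(g) {
      sort(names(idx)[vapply(idx, function(v) g %in% v, logical(1))])
    })
    names(back) <- genes
    expect_equal(back, sig)
    expect_equal(sum(lengths(idx)), sum(lengths(sig)))
  }
  expect_length(build_combination_index(list(a = character(0))), 0L)
})

test_that("must-link derivation chains identical nonempty signatures only", {
  sig <- list(a = "X/RpoD:activation", b = "X/RpoD:activation",
              c = "X/RpoD:activation", d = "Y/RpoD:activation",
              e = character(0), f = character(0))
  cs <- derive_mustlinks(sig, c("a", "b", "c", "d", "e", "f"))
  # 3-gene identical group -> 2 chain links; empty signatures never linked
  expect_equal(nrow(cs$must_links), 2L)
  expect_setequal(c(cs$must_links), c("a", "b", "c"))
  # all distinct -> no links
  expect_equal(nrow(derive_mustlinks(list(a = "X:1", b = "Y:1"),
                                     c("a", "b"))$must_links), 0L)
  # non-DEG genes never linked
  cs2 <- derive_mustlinks(sig, c("a", "b"))
  expect_true(all(c(cs2$must_links) %in% c("a", "b")))
  # max_pairs truncates deterministically, largest groups kept
  sig3 <- c(sig, list(g = "X/RpoD:activation"))
  cs3 <- derive_mustlinks(sig3, names(sig3), max_pairs = 2L)
  expect_equal(nrow(cs3$must_links), 2L)
  # first two links of the 4-gene chain a-b, b-c, c-g survive
  expect_setequal(c(cs3$must_links), c("a", "b", "c"))
  expect_error(derive_mustlinks(sig, names(sig), max_pairs = 0L), "max_pairs")
  expect_error(constraint_set(must_links = rbind(c("a", "b")),
                              cannot_links = rbind(c("b", "a"))), "both")
})
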