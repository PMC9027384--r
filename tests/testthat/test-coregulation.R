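imp <- c("A/RpoD:activation", "B/RpoD:repression", "C/RpoS:activation")

toy_levels <- function() {
  sig <- list(
    g1 = imp[1],                              # level 1
    g2 = c(imp[1], "Zzz/RpoD:activation"),    # non-important combo ignored
    g3 = c(imp[1], imp[2]),                   # level 2
    g4 = c(imp[1], imp[2]),
    g5 = imp[3],                              # level 1 (other combo)
    g6 = "Zzz/RpoD:activation"                # only unimportant -> excluded
  )
  x <- time_course_matrix(rbind(
    g1 = c(-2, -1.8, -0.5), g2 = c(-2.2, -1.5, -0.2),
    g3 = c(2.0, 1.8, 0.4), g4 = c(1.8, 2.1, 0.2),
    g5 = c(0.1, 1.9, 2.2), g6 = c(-1.6, -0.2, 0)),
    times = c(1, 4, 12))
  list(sig = sig, x = x)
}

test_that("level groups equal brute-force powerset bucketing", {
  t <- toy_levels()
  groups <- assign_levels(names(t$sig), imp, t$sig, t$x)
  df <- as.data.frame(groups)
  # oracle: bucket genes by their exact important-subset by hand
  buckets <- split(names(t$sig),
                   vapply(t$sig, function(s) paste(sort(intersect(s, imp)),
                                                   collapse = " + "),
                          character(1)))
  buckets <- buckets[nzchar(names(buckets))]
  expect_setequal(df$group, names(buckets))
  for (g in groups) expect_setequal(g$genes, buckets[[g$id]])
  expect_equal(df$level[match(imp[1], df$group)], 1L)
  expect_equal(df$level[match(paste(sort(imp[1:2]), collapse = " + "),
                              df$group)], 2L)
  # g6 excluded; groups partition the important-controlled genes
  expect_false("g6" %in% unlist(lapply(groups, `[[`, "genes")))
  expect_equal(sum(df$n_genes),
               sum(vapply(t$sig, function(s) length(intersect(s, imp)) > 0,
                          logical(1))))
  expect_equal(df$direction[match(imp[1], df$group)], "down")
  # singleton groups retained but untestable
  expect_false(groups[[which(df$group == imp[3])]]$testable)
  expect_error(assign_levels("g1", character(0), t$sig, t$x), "important")
})

test_that("group Fisher rewards direction-coherent groups", {
  set.seed(4)
  n <- 120
  ids <- sprintf("g%03d", 1:n)
  x <- time_course_matrix(matrix(rnorm(n * 3, 0, 0.2), n), ids, times = 1:3)
  x[1:50, ] <- x[1:50, ] - 2.5          # down-regulated DEGs
  x[51:100, ] <- x[51:100, ] + 2.5      # up-regulated DEGs
  x[11:12, ] <- x[11:12, ] - 0.2        # slightly stronger down pair
  deg <- filter_degs(x, 1.5)
  sig <- c(
    stats::setNames(rep(list(imp[1]), 10), ids[1:10]),  # coherent down group
    # 2 down + 2 up: direction mix matches the 50/50 background
    stats::setNames(rep(list(imp[2]), 4), ids[c(11, 12, 51, 52)])
  )
  groups <- assign_levels(deg, imp[1:2], sig, x)
  groups <- group_fisher(groups, x, deg)
  df <- as.data.frame(groups)
  expect_lt(df$fisher_p_adj[df$group == imp[1]], 1e-3)
  expect_gt(df$fisher_p_adj[df$group == imp[2]], 0.3)
  # the background-like table agrees with the enumeration oracle
  g2 <- groups[[which(df$group == imp[2])]]
  K <- sum(gene_directions(x)[deg$gene_ids] == g2$direction)
  expect_equal(g2$fisher_p_raw, fisher_enum(2, 4, K, n), tolerance = 1e-12)
})

test_that("group Fisher degenerate margins give p = 1 with a warning", {
  t <- toy_levels()
  groups <- assign_levels(names(t$sig), imp, t$sig, t$x)
  # a universe with no DEG in the group's direction
  expect_warning(
    g2 <- group_fisher(groups[1], t$x, character(0)),
    "degenerate")
  expect_equal(g2[[1]]$fisher_p_raw, 1)
})

test_that("pooled t-tests match the closed form and the symmetric null", {
  # frozen oracle: group (1.0, 1.2, 0.8) vs complement (0.0, 0.1, -0.1, 0.0)
  x <- time_course_matrix(
    matrix(c(1.0, 1.2, 0.8, 0.0, 0.1, -0.1, 0.0), ncol = 1),
    genes = sprintf("g%d", 1:7), times = 1)
  sig <- stats::setNames(rep(list(imp[1]), 3), sprintf("g%d", 1:3))
  groups <- assign_levels(sprintf("g%d", 1:3), imp[1], sig, x)
  tt <- timepoint_ttests(groups, x)
  expect_equal(tt$t_stat, 9.258200997726, tolerance = 1e-9)
  expect_equal(tt$p_one_sided, 1.235465831354e-04, tolerance = 1e-9)
  expect_equal(tt$p_adj, tt$p_one_sided)  # single test in the level
  # group equal to complement -> t = 0, one-sided p = 0.5
  x0 <- time_course_matrix(matrix(c(1, 2, 1, 2), ncol = 1),
                           genes = sprintf("h%d", 1:4), times = 1)
  sig0 <- stats::setNames(rep(list(imp[1]), 2), c("h1", "h2"))
  g0 <- assign_levels(c("h1", "h2"), imp[1], sig0, x0)
  tt0 <- timepoint_ttests(g0, x0)
  expect_equal(tt0$t_stat, 0)
  expect_equal(tt0$p_one_sided, 0.5)
  # closed-form agreement on random samples, and one-sided = two-sided / 2
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1), mean = 1)
    b <- rnorm(sample(3:8, 1))
    ids <- sprintf("r%02d", seq_len(length(a) + length(b)))
    xi <- time_course_matrix(matrix(c(a, b), ncol = 1), ids, times = 1)
    sigi <- stats::setNames(rep(list(imp[1]), length(a)), ids[seq_along(a)])
    gi <- assign_levels(ids[seq_along(a)], imp[1], sigi, xi)
    tti <- timepoint_ttests(gi, xi)
    t_ref <- pooled_t(a, b)
    df_ref <- length(a) + length(b) - 2
    dir_up <- mean(a) >= 0
    p_ref <- if (dir_up) pt(t_ref, df_ref, lower.tail = FALSE)
             else pt(t_ref, df_ref)
    expect_equal(tti$t_stat, t_ref, tolerance = 1e-12)
    expect_equal(tti$p_one_sided, p_ref, tolerance = 1e-12)
    p_two <- 2 * pt(-abs(t_ref), df_ref)
    if ((t_ref > 0) == dir_up) {
      expect_equal(tti$p_one_sided, p_two / 2, tolerance = 1e-12)
    }
  }
})

test_that("decisive needs both corrected p-values under the cutoff", {
  mk <- function(fp) structure(list(list(id = "G", combos = "G", level = 1L,
                                         genes = c("a", "b"), direction = "down",
                                         testable = TRUE, fisher_p_raw = fp,
                                         fisher_p_adj = fp, decisive = FALSE)),
                               class = "level_groups")
  tt <- data.frame(group = "G", level = 1L, time = 1, direction = "down",
                   t_stat = -3, p_one_sided = 0.01, p_adj = 0.2)
  expect_false(decisive_flags(mk(0.04), tt)[[1]]$decisive)   # t-test fails
  tt$p_adj <- 0.01
  expect_true(decisive_flags(mk(0.01), tt)[[1]]$decisive)    # both pass
  expect_false(decisive_flags(mk(0.2), tt)[[1]]$decisive)    # fisher fails
})

test_that("heat-map export round-trips values and signs", {
  io <- small_inputs()
  deg <- filter_degs(io$x, 1.5)
  sig <- build_signatures(io$net$interactions, rownames(io$x))
  res <- coregulation_analysis(deg, planted_combo_keys(io$truth), sig, io$x)
  tt <- res$ttests
  expect_gt(nrow(tt), 0)
  p <- tempfile(fileext = ".tsv")
  export_heatmap(tt, p)
  back <- read.delim(p, check.names = FALSE)
  times <- sort(unique(tt$time))
  expect_equal(as.numeric(colnames(back)[-(1:2)]), times)
  for (i in seq_len(nrow(back))) {
    sub <- tt[tt$group == back$group[i], ]
    expect_equal(as.numeric(back[i, -(1:2)]),
                 sub$signed_log10_p[match(times, sub$time)],
                 tolerance = 1e-9)
  }
  # signs follow group direction everywhere
  expect_true(all(sign(tt$signed_log10_p[tt$direction == "down"]) <= 0))
  expect_true(all(sign(tt$signed_log10_p[tt$direction == "up"]) >= 0))
  # no testable groups -> header-only file
  export_heatmap(tt[0, ], p)
  expect_length(readLines(p), 1L)
})
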