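# Independent naive O(n^3) agglomerative clustering over matrix columns,
# used as an oracle for cluster_oncogenes().
naive_complete_linkage <- function(m) {
  d <- as.matrix(dist(t(m)))
  active <- as.list(seq_len(ncol(m)))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[active[[i]], active[[j]]])  # complete linkage
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  heights
}

test_that("oncogene clustering reproduces the hierarchical merge structure", {
  m <- cbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(9, 9, 9))
  tree <- cluster_oncogenes(m)
  expect_equal(tree$height[1], 0)
  expect_setequal(tree$labels[-tree$merge[1, ]], c("A", "B"))

  set.seed(12)
  r <- matrix(rnorm(300), ncol = 6, dimnames = list(NULL, LETTERS[1:6]))
  tree_r <- cluster_oncogenes(r)
  expect_equal(sort(tree_r$height), sort(naive_complete_linkage(r)))

  # column permutation leaves the merge heights unchanged
  perm <- r[, c(4, 2, 6, 1, 3, 5)]
  expect_equal(sort(cluster_oncogenes(perm)$height), sort(tree_r$height))

  # an all-zero feature row adds nothing to any squared distance
  with_zero <- rbind(r, 0)
  expect_equal(cluster_oncogenes(with_zero)$height, tree_r$height)
  expect_equal(cluster_oncogenes(with_zero)$merge, tree_r$merge)

  # missing values are imputed to "no change" before distances
  r_na <- r
  r_na[1, 1] <- NA
  r0 <- r
  r0[1, 1] <- 0
  expect_equal(cluster_oncogenes(r_na)$height, cluster_oncogenes(r0)$height)

  expect_error(cluster_oncogenes(r[, 1, drop = FALSE]), "at least 2")
})

test_that("Venn region counts are exact and conserve set sizes", {
  simple <- venn_counts(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(simple$count[match(c("A", "B", "A&B"), simple$region)],
               c(1L, 1L, 1L))

  same <- venn_counts(setNames(rep(list(letters[1:7]), 6), LETTERS[1:6]))
  expect_equal(sum(same$count), 7)
  expect_equal(same$count[same$region == paste(LETTERS[1:6], collapse = "&")],
               7L)
  expect_true(all(same$count[same$region != paste(LETTERS[1:6],
                                                  collapse = "&")] == 0L))

  # random instance against a brute-force set-algebra oracle
  set.seed(13)
  sets <- lapply(1:6, function(i) sample(1:200, sample(20:120, 1)))
  names(sets) <- LETTERS[1:6]
  regions <- venn_counts(sets)
  for (i in seq_len(nrow(regions))) {
    members <- strsplit(regions$region[i], "&", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, sets[members])
    for (out in setdiff(names(sets), members)) {
      inside <- setdiff(inside, sets[[out]])
    }
    expect_equal(regions$count[i], length(inside))
  }
  # conservation: regions partition the union; marginals recover set sizes
  expect_equal(sum(regions$count), length(unique(unlist(sets))))
  for (nm in names(sets)) {
    has <- vapply(strsplit(regions$region, "&", fixed = TRUE),
                  function(m) nm %in% m, logical(1))
    expect_equal(sum(regions$count[has]), length(unique(sets[[nm]])))
  }

  expect_error(venn_counts(c(list(X = 1), setNames(rep(list(1), 6),
                                                   LETTERS[1:6]))), "1 to 6")
})

test_that("common targets are ranked by the number of calling oncogenes", {
  consensus <- tidyr::expand_grid(feature = c("f1", "f2", "f3"),
                                  condition = default_oncogenes())
  consensus$avg_ratio <- 1.5
  consensus$avg_confidence <- 0.96
  consensus$call <- "none"
  consensus$call[consensus$feature == "f1"] <- "up"                 # 6 calls
  consensus$call[consensus$feature == "f2"][1:4] <- "up"            # 4 calls
  consensus$call[consensus$feature == "f3"][1:3] <- "down"          # 3 calls

  top <- common_targets(consensus, min_oncogenes = 4)
  expect_setequal(unique(top$feature), c("f1", "f2"))
  expect_equal(unique(top$n_changed[top$feature == "f1"]), 6)
  expect_identical(unique(top$feature)[1], "f1")  # sorted by call count

  expect_setequal(unique(common_targets(consensus, 1)$feature),
                  c("f1", "f2", "f3"))
  expect_equal(nrow(common_targets(consensus, 7)), 0)

  wide <- format_common_targets(top)
  expect_equal(nrow(wide), 2)
  # uncalled cells carry the bracketed-confidence convention
  expect_match(wide[wide$feature == "f2", ][["FLT3ITD"]], "\\(0\\.96\\)")
  expect_match(wide[wide$feature == "f1", ][["FLT3ITD"]], "^1.50 0.96$")
})

test_that("percent reduction is the rounded complement of the fold", {
  expect_equal(percent_reduction(0.72), 28)
  expect_equal(percent_reduction(1.0), 0)
  expect_equal(percent_reduction(0.51), 49)
  expect_equal(percent_reduction(1.25), -25)
  expect_error(percent_reduction(0), "> 0")
})

test_that("the consensus log2 matrix feeds clustering with NA-safe entries", {
  study <- tiny_study(spike_fraction = 0.3)
  res <- call_study(study)
  m <- consensus_log2_matrix(res$consensus)
  expect_equal(ncol(m), 6)
  expect_equal(nrow(m), 60)
  tree <- cluster_oncogenes(m)
  expect_s3_class(tree, "hclust")
  expect_setequal(tree$labels, default_oncogenes())
})
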