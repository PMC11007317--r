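test_that("electrode-wise Pearson map reproduces hand-computed values", {
  mont <- mini_montage()
  scores <- c(1, 2, 3, 4)
  maps <- matrix(rnorm(4 * 12), 4, dimnames = list(NULL, mont$label))
  maps[, 1] <- scores                 # r = 1
  maps[, 2] <- -scores                # r = -1
  maps[, 3] <- c(1, 3, 2, 4)          # textbook example: r = 0.8
  ds <- swa_dataset(maps, scores, mont = mont)
  rmap <- pearson_map(ds)
  expect_equal(rmap$r[1], 1)
  expect_equal(rmap$r[2], -1)
  expect_equal(rmap$r[3], 0.8)
  expect_true(all(abs(rmap$r) <= 1))

  maps[, 4] <- 7                       # zero variance
  expect_error(pearson_map(swa_dataset(maps, scores, mont = mont)),
               regexp = mont$label[4])
})

test_that("the correlation map is invariant to linear transforms", {
  mont <- mini_montage()
  set.seed(16)
  maps <- matrix(rnorm(10 * 12), 10, dimnames = list(NULL, mont$label))
  scores <- rnorm(10)
  r1 <- pearson_map(swa_dataset(maps, scores, mont = mont))$r
  r2 <- pearson_map(swa_dataset(maps, 3 * scores + 2, mont = mont))$r
  maps2 <- maps
  maps2[, 5] <- 0.1 * maps[, 5] + 7
  r3 <- pearson_map(swa_dataset(maps2, scores, mont = mont))$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("critical r matches the t-quantile relation", {
  tq <- qt(1 - 0.05 / 2, df = 52)
  expect_equal(critical_r(54, 0.05), tq / sqrt(tq^2 + 52), tolerance = 1e-12)
  expect_equal(critical_r(54, 0.05), 0.2681, tolerance = 1e-4)
  expect_lt(critical_r(54, 0.999), 1e-3)         # alpha -> 1 limit
  rs <- vapply(c(10, 20, 54, 200), critical_r, 0)
  expect_true(all(diff(rs) < 0))                 # decreasing in n
  expect_error(critical_r(54, 1.2), class = "swatopo_parameter_error")
})

test_that("adjacency graph thresholds Euclidean distance symmetrically", {
  mont <- mini_montage()
  d <- as.matrix(dist(as.matrix(mont[, c("x", "y", "z")])))
  diag(d) <- Inf
  empty <- adjacency_graph(mont, min(d) - 1)
  expect_true(all(lengths(empty$neighbors) == 0))
  full <- adjacency_graph(mont, max(d) + 1)
  expect_true(all(lengths(full$neighbors) == 11))
  g <- adjacency_graph(mont, 40)
  for (i in seq_along(g$neighbors)) {
    for (j in g$neighbors[[i]]) expect_true(i %in% g$neighbors[[j]])
    expect_false(i %in% g$neighbors[[i]])
  }
  expect_error(adjacency_graph(mont, 0), class = "swatopo_parameter_error")
})

test_that("three collinear electrodes at spacing d and threshold 1.5d chain up", {
  r <- 85
  ang <- 20 * pi / 180                     # arc step along a meridian
  mont <- montage(tibble::tibble(
    label = c("a", "b", "c"),
    x = r * sin(c(-ang, 0, ang)), y = 0, z = r * cos(c(-ang, 0, ang))
  ), head_radius = r)
  d <- sqrt(sum((as.numeric(mont[1, 2:4]) - as.numeric(mont[2, 2:4]))^2))
  g <- adjacency_graph(mont, 1.5 * d)
  expect_identical(lengths(g$neighbors), c(1L, 2L, 1L))
})

test_that("cluster finding separates signs and matches brute force", {
  r <- 85
  ang <- (1:4) * 15 * pi / 180
  mont <- montage(tibble::tibble(
    label = paste0("e", 1:4),
    x = r * sin(ang), y = 0, z = r * cos(ang)
  ), head_radius = r)
  step <- sqrt(sum((as.numeric(mont[1, 2:4]) - as.numeric(mont[2, 2:4]))^2))
  g <- adjacency_graph(mont, 1.2 * step)   # chain e1-e2-e3-e4
  rmap <- tibble::tibble(electrode = paste0("e", 1:4),
                         r = c(0.5, 0.6, 0.1, 0.7))
  cl <- find_clusters(rmap, g, 0.3)
  expect_identical(cl$size, c(2L, 1L))
  expect_setequal(cl$electrodes[[1]], c("e1", "e2"))
  expect_setequal(cl$electrodes[[2]], "e4")

  # adjacent but opposite-sign electrodes stay separate
  rmap2 <- tibble::tibble(electrode = paste0("e", 1:4),
                          r = c(0.5, -0.5, 0, 0))
  cl2 <- find_clusters(rmap2, g, 0.3)
  expect_identical(cl2$size, c(1L, 1L))
  expect_identical(sort(cl2$sign), c(-1L, 1L))

  empty <- find_clusters(tibble::tibble(electrode = paste0("e", 1:4),
                                        r = rep(0, 4)), g, 0.3)
  expect_identical(nrow(empty), 0L)
})

test_that("exhaustive permutation p-values equal brute-force enumeration", {
  skip_if_not_installed("igraph")
  mont <- mini_montage()
  set.seed(17)
  n <- 6
  maps <- matrix(rnorm(n * 12), n, dimnames = list(NULL, mont$label))
  maps[, 1:3] <- maps[, 1:3] + 2 * rnorm(n)   # induce some structure
  scores <- rnorm(n)
  ds <- swa_dataset(maps, scores, mont = mont)
  g <- adjacency_graph(mont, 40)
  ct <- cluster_permutation_test(ds, g)
  expect_true(ct$exhaustive)
  expect_identical(ct$n_permutations, 720L)

  # independent oracle: recursive enumeration, cor(), igraph components
  adj <- matrix(FALSE, 12, 12, dimnames = list(mont$label, mont$label))
  dm <- as.matrix(dist(as.matrix(mont[, c("x", "y", "z")])))
  adj[dm <= 40] <- TRUE
  diag(adj) <- FALSE
  rc <- critical_r(n, 0.05)
  max_size <- function(sc) {
    r <- as.numeric(cor(maps, sc))
    supra <- which(abs(r) >= rc)
    if (!length(supra)) return(0L)
    sub <- adj[supra, supra, drop = FALSE] &
      outer(sign(r[supra]), sign(r[supra]), "==")
    gr <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    as.integer(max(igraph::components(gr)$csize))
  }
  permute_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  null_sizes <- vapply(permute_all(scores), max_size, 0L)
  expect_identical(sort(null_sizes), sort(as.integer(ct$null_max_sizes)))
  for (i in seq_len(nrow(ct$clusters))) {
    want <- (1 + sum(null_sizes >= ct$clusters$size[i])) / (1 + 720)
    expect_identical(ct$clusters$p_value[i], want)
  }
})

test_that("the permutation test is reproducible under a fixed seed", {
  mont <- mini_montage()
  set.seed(18)
  maps <- matrix(rnorm(20 * 12), 20, dimnames = list(NULL, mont$label))
  ds <- swa_dataset(maps, rnorm(20), mont = mont)
  g <- adjacency_graph(mont, 40)
  a <- cluster_permutation_test(ds, g, n_permutations = 300, seed = 9)
  b <- cluster_permutation_test(ds, g, n_permutations = 300, seed = 9)
  expect_identical(a$null_max_sizes, b$null_max_sizes)
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a)$critical_cluster_size, a$critical_cluster_size)
  expect_error(cluster_permutation_test(ds, g, n_permutations = 50),
               class = "swatopo_parameter_error")
})

test_that("cluster p-values honour the add-one permutation convention", {
  mont <- mini_montage()
  set.seed(19)
  maps <- matrix(rnorm(15 * 12), 15, dimnames = list(NULL, mont$label))
  maps[, 1:4] <- maps[, 1:4] + 3 * rnorm(15)    # strong planted signal
  ds <- swa_dataset(maps, rowMeans(maps[, 1:4]), mont = mont)
  ct <- cluster_permutation_test(ds, adjacency_graph(mont, 40),
                                 n_permutations = 400, seed = 2)
  expect_true(all(ct$clusters$p_value >= 1 / 401))
  expect_true(all(ct$clusters$p_value <= 1))
  for (i in seq_len(nrow(ct$clusters))) {
    expect_equal(ct$clusters$p_value[i],
                 (1 + sum(ct$null_max_sizes >= ct$clusters$size[i])) / 401)
  }
  # every cluster electrode is suprathreshold
  for (el in unlist(ct$clusters$electrodes)) {
    expect_gte(abs(ct$r_map$r[ct$r_map$electrode == el]), ct$r_critical)
  }
})

test_that("cluster-mean correlation and its mapping to R^2 and p", {
  mont <- mini_montage()
  set.seed(20)
  maps <- matrix(rnorm(12 * 12), 12, dimnames = list(NULL, mont$label))
  scores <- rnorm(12)
  ds <- swa_dataset(maps, scores, mont = mont)
  one <- cluster_mean_correlation(ds, "P4")
  expect_equal(one$r, pearson_map(ds)$r[mont$label == "P4"])
  expect_equal(one$r_squared, one$r^2)
  expect_equal(one$df, 10)
  # perfect correlation: p collapses to 0
  ds2 <- swa_dataset(maps, maps[, 2], mont = mont)
  perfect <- cluster_mean_correlation(ds2, mont$label[2])
  expect_lt(perfect$p_value, 1e-12)
  expect_error(cluster_mean_correlation(ds, character()),
               class = "swatopo_parameter_error")
})

test_that("partial correlation equals simple correlation for orthogonal
           covariates and matches the textbook formula", {
  set.seed(21)
  n <- 40
  x0 <- rnorm(n); y0 <- rnorm(n); z <- rnorm(n)
  # orthogonalize x and y against [1, z]
  x <- residuals(lm(x0 ~ z))
  y <- residuals(lm(y0 ~ z))
  simple <- cor(x, y)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, simple, tolerance = 1e-12)
  expect_equal(pc$df, n - 3)

  # textbook 1-covariate formula on raw (non-orthogonal) data
  a <- rnorm(n); b <- rnorm(n); c0 <- rnorm(n)
  rxy <- cor(a, b); rxz <- cor(a, c0); ryz <- cor(b, c0)
  want <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_correlation(a, b, c0)$r, want, tolerance = 1e-12)

  expect_error(partial_correlation(a, b, a),
               class = "swatopo_validation_error")
  expect_error(partial_correlation(a, b, cbind(c0, 2 * c0)),
               class = "swatopo_validation_error")
})

test_that("per-cycle analysis reduces to the whole-night result for
           identical cycles", {
  mont <- mini_montage()
  set.seed(22)
  n <- 16
  base <- matrix(rnorm(n * 12, sd = 0.2), n, dimnames = list(NULL, mont$label))
  rel <- exp(base); rel <- rel / rowMeans(rel)
  logmaps <- log(rel)
  scores <- rnorm(n)
  cycle_maps <- lapply(seq_len(n), function(i) {
    m <- topomap(stats::setNames(logmaps[i, ], mont$label), "log_relative")
    list(cycle_1 = m, cycle_2 = m, cycle_3 = m, cycle_4 = m)
  })
  res <- per_cycle_analysis(cycle_maps, scores, c("P4", "P6"), mont)
  whole <- cluster_mean_correlation(
    swa_dataset(logmaps, scores, mont = mont), c("P4", "P6"))
  expect_equal(res$per_cycle$r, rep(whole$r, 4))
  expect_equal(res$pooled$r, whole$r)

  broken <- cycle_maps
  broken[[3]]$cycle_4 <- NULL
  expect_error(per_cycle_analysis(broken, scores, "P4", mont), "3")
})

test_that("planted per-cycle effects are recovered near the planted strength", {
  mont <- mini_montage()
  set.seed(23)
  n <- 200
  rho <- 0.5
  cl <- c("P4", "P6")
  u <- rnorm(n)
  scores <- rho * u + sqrt(1 - rho^2) * rnorm(n)
  cycle_maps <- lapply(seq_len(n), function(i) {
    out <- lapply(1:4, function(cyc) {
      v <- rnorm(12, sd = 0.2)
      names(v) <- mont$label
      v[cl] <- v[cl] + 0.4 * u[i]
      rel <- exp(v); rel <- rel / mean(rel)
      topomap(rel, "relative") |> log_map()
    })
    names(out) <- sprintf("cycle_%d", 1:4)
    out
  })
  res <- per_cycle_analysis(cycle_maps, scores, cl, mont)
  # each cycle's r within sampling error of the planted association
  expect_true(all(abs(res$per_cycle$r - rho * 0.8) < 0.15))
  expect_gt(res$pooled$r, max(res$per_cycle$r) - 0.05)  # pooling denoises
})
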