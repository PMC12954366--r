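test_that("three channels form a fully connected triangle", {
  mon <- montage(c("C1", "C3", "C5"),
                 rbind(c(0.1, 0.2, 0.97), c(-0.4, 0.1, 0.9),
                       c(-0.7, 0, 0.7)))
  adj <- build_adjacency(mon)
  expect_true(all(adj))
})

test_that("four channels at square corners give 2-3 neighbours each", {
  mon <- montage(paste0("C", 1:4),
                 rbind(c(0.3, 0.3, 0.9), c(-0.3, 0.3, 0.9),
                       c(-0.3, -0.3, 0.9), c(0.3, -0.3, 0.9)))
  adj <- build_adjacency(mon)
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj)))
  deg <- rowSums(adj) - 1
  expect_true(all(deg >= 2 & deg <= 3))
})

test_that("vertex channel neighbours its surrounding ring", {
  adj <- std_adjacency()
  expect_true(all(c("C1", "C2", "FCz", "CPz") %in%
                    channel_neighborhood(adj, "Cz")))
  expect_true(isSymmetric(adj))
  expect_true(all(diag(adj)))
  expect_true(all(rowSums(adj) >= 2)) # everyone has a neighbour
})

test_that("adjacency is invariant to channel ordering", {
  mon <- std_montage()
  set.seed(42)
  perm <- sample(length(mon$channels))
  mon2 <- montage(mon$channels[perm], mon$positions[perm, ])
  adj1 <- build_adjacency(mon)
  adj2 <- build_adjacency(mon2)
  expect_identical(adj1, adj2[mon$channels, mon$channels])
})

test_that("triangulation edges satisfy the empty-circumcircle property", {
  # brute-force oracle: collect edges of every triangle whose
  # circumcircle contains no other point
  oracle_delaunay_edges <- function(xy) {
    n <- nrow(xy)
    edges <- matrix(FALSE, n, n)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      ax <- xy[i, 1]; ay <- xy[i, 2]
      bx <- xy[j, 1]; by <- xy[j, 2]
      cx <- xy[k, 1]; cy <- xy[k, 2]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      r2 <- (ax - ux)^2 + (ay - uy)^2
      others <- setdiff(seq_len(n), c(i, j, k))
      inside <- (xy[others, 1] - ux)^2 + (xy[others, 2] - uy)^2 <
        r2 * (1 - 1e-9)
      if (!any(inside)) {
        edges[i, j] <- edges[j, i] <- TRUE
        edges[i, k] <- edges[k, i] <- TRUE
        edges[j, k] <- edges[k, j] <- TRUE
      }
    }
    edges
  }
  for (seed in 1:3) {
    set.seed(seed)
    n <- 12
    # random points on the upper hemisphere, generic position
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    u[, 3] <- abs(u[, 3]) + 0.2
    u <- u / sqrt(rowSums(u^2))
    mon <- montage(paste0("C", seq_len(n)), u)
    adj <- build_adjacency(mon)
    xy <- project_scalp(mon)
    want <- oracle_delaunay_edges(xy)
    diag(want) <- TRUE
    expect_identical(unname(adj), want)
  }
})

test_that("degenerate montages are rejected", {
  mon <- montage(c("C1", "C2", "C3"),
                 rbind(c(0.1, 0.2, 0.97), c(0.1, 0.2, 0.97),
                       c(-0.7, 0, 0.7)))
  expect_error(build_adjacency(mon), "Degenerate")
  expect_error(
    build_adjacency(montage(c("a", "b"), rbind(c(0, 1, 0), c(1, 0, 0)))),
    "at least 3")
})
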