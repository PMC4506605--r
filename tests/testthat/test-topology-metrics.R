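test_that("degrees satisfy the textbook identities", {
  k4 <- random_test_network(4, 1.1, seed = 1)  # complete
  expect_true(all(node_degrees(k4) == 3))
  star <- pin_network(c("hub", paste0("l", 1:5)),
                      cbind("hub", paste0("l", 1:5)))
  d <- node_degrees(star)
  expect_equal(unname(d["hub"]), 5L)
  expect_true(all(d[paste0("l", 1:5)] == 1L))
  g <- random_test_network(30, 0.15, seed = 2)
  expect_equal(sum(node_degrees(g)), 2L * igraph::ecount(g))
})

test_that("betweenness matches hand values on canonical graphs", {
  p3 <- pin_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  bc <- node_betweenness(p3)
  expect_equal(unname(bc[c("A", "B", "C")]), c(0, 1, 0))

  star <- pin_network(c("hub", paste0("l", 1:6)),
                      cbind("hub", paste0("l", 1:6)))
  bc <- node_betweenness(star)
  expect_equal(unname(bc["hub"]), 1)
  expect_true(all(bc[paste0("l", 1:6)] == 0))

  ring <- pin_network(paste0("c", 1:5),
                      cbind(paste0("c", 1:5), paste0("c", c(2:5, 1))))
  bc <- node_betweenness(ring)
  oracle <- oracle_betweenness(ring)
  expect_true(max(abs(bc[names(oracle)] - oracle)) < 1e-9)
  expect_lt(diff(range(bc)), 1e-12)  # all five nodes equivalent

  # fewer than three nodes: no interior pairs
  expect_true(all(node_betweenness(pin_network(c("A", "B"),
                                               rbind(c("A", "B")))) == 0))
})

test_that("closeness matches hand values and handles isolates", {
  k5 <- random_test_network(5, 1.1, seed = 3)
  expect_true(all(abs(node_closeness(k5) - 1) < 1e-12))
  p3 <- pin_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  cc <- node_closeness(p3)
  expect_equal(unname(cc[c("A", "B", "C")]), c(2 / 3, 1, 2 / 3))
  iso <- pin_network(c("A", "B", "C"), rbind(c("A", "B")))
  expect_equal(unname(node_closeness(iso)["C"]), 0)
})

test_that("betweenness and closeness agree with BFS oracles on random graphs", {
  cases <- expand.grid(seed = 1:5, n = c(12, 25, 40), p = c(0.08, 0.2))
  for (i in seq_len(nrow(cases))) {
    net <- random_test_network(cases$n[i], cases$p[i],
                               seed = cases$seed[i] + 1000 * i)
    bc <- node_betweenness(net)
    cc <- node_closeness(net)
    obc <- oracle_betweenness(net)
    occ <- oracle_closeness(net)
    expect_lt(max(abs(bc[names(obc)] - obc)), 1e-9)
    expect_lt(max(abs(cc[names(occ)] - occ)), 1e-9)
  }
})

test_that("metrics are invariant under node relabeling", {
  net <- random_test_network(30, 0.12, seed = 8)
  nodes <- igraph::V(net)$name
  set.seed(1)
  perm <- sample(nodes)
  relabeled <- pin_network(perm, as.matrix(gametePIN:::.edge_df(net)))
  for (metric in list(node_degrees, node_betweenness, node_closeness)) {
    a <- metric(net); b <- metric(relabeled)
    expect_equal(a[nodes], b[nodes], tolerance = 1e-12)
  }
})

# the closeness part of this property needs a connected graph: with
# component-restricted closeness, bridging into a distant component can
# lower the bridging endpoints' mean reachable distance denominator
test_that("adding an edge never hurts degree or endpoint closeness", {
  for (seed in 1:3) {
    net <- random_test_network(20, 0.25, seed)
    if (!igraph::is_connected(net)) {
      ring <- igraph::V(net)$name
      net <- union_networks(net, pin_network(ring, cbind(ring, ring[c(2:20, 1)])))
    }
    nodes <- igraph::V(net)$name
    adj <- oracle_adjacency(net)
    non_edges <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
    set.seed(seed)
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    u <- rownames(adj)[pick[1]]; v <- colnames(adj)[pick[2]]
    bigger <- union_networks(net, pin_network(c(u, v), rbind(c(u, v))))
    expect_true(all(node_degrees(bigger)[nodes] >= node_degrees(net)[nodes]))
    cc0 <- node_closeness(net); cc1 <- node_closeness(bigger)
    expect_gte(cc1[[u]], cc0[[u]])
    expect_gte(cc1[[v]], cc0[[v]])
  }
})

test_that("path statistics enumerate connected pairs correctly", {
  k4 <- random_test_network(4, 1.1, seed = 4)
  ps <- path_stats(k4)
  expect_equal(ps$characteristic_path_length, 1)
  expect_equal(sum(ps$histogram), 6)

  p4 <- pin_network(c("A", "B", "C", "D"),
                    rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  ps <- path_stats(p4)
  expect_equal(ps$histogram, setNames(c(3L, 2L, 1L), c("1", "2", "3")))
  expect_equal(ps$characteristic_path_length, 10 / 6)

  two <- pin_network(c("A", "B", "C", "D"), rbind(c("A", "B"), c("C", "D")))
  ps <- path_stats(two)
  expect_equal(ps$histogram, setNames(2L, "1"))
  expect_equal(ps$characteristic_path_length, 1)

  lone <- pin_network(c("A", "B"))
  ps <- path_stats(lone)
  expect_length(ps$histogram, 0)
  expect_true(is.na(ps$characteristic_path_length))
})

test_that("histogram totals equal component-pair arithmetic", {
  for (seed in 1:5) {
    net <- random_test_network(35, 0.06, seed)
    ps <- path_stats(net)
    sizes <- igraph::components(net)$csize
    expect_equal(sum(ps$histogram), sum(choose(sizes, 2)))
  }
})

test_that("power-law fit is exact on exact power laws", {
  deg <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  fit <- fit_power_law(deg)
  expect_equal(fit$exponent, -2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_points, 4)

  flat <- rep(c(1, 2, 3), times = c(10, 10, 10))
  expect_equal(fit_power_law(flat)$exponent, 0, tolerance = 1e-12)

  expect_error(fit_power_law(rep(3, 10)), "at least 2")
  expect_error(fit_power_law(c(0, 0, 2)), "at least 2")
})

test_that("fit coefficients equal a closed-form OLS recomputation", {
  for (seed in 1:5) {
    set.seed(seed)
    deg <- rpois(300, 4)
    fit <- fit_power_law(deg)
    kpos <- deg[deg > 0]
    tab <- table(kpos)
    x <- log10(as.numeric(names(tab)))
    y <- log10(as.numeric(tab) / length(deg))
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
    r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
    expect_equal(fit$exponent, slope, tolerance = 1e-9)
    expect_equal(fit$intercept, intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, r2, tolerance = 1e-9)
  }
})

test_that("preferential-attachment degree spectra fit a negative slope", {
  g <- generate_powerlaw_network(2000, 2, seed = 11)
  fit <- fit_power_law(node_degrees(g))
  expect_lt(fit$exponent, -1)
  expect_gt(fit$r_squared, 0.6)
})

test_that("centrality tables carry one row per node with symbols attached", {
  net <- random_test_network(15, 0.2, seed = 6)
  ann <- simple_annotations(igraph::V(net)$name)
  tbl <- centrality_table(net, ann)
  expect_equal(nrow(tbl), 15)
  expect_setequal(tbl$accession, igraph::V(net)$name)
  expect_equal(tbl$gene_symbol, paste0("g", tbl$accession))
  expect_equal(sum(tbl$degree), 2 * igraph::ecount(net))
})
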