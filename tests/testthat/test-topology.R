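path_net <- function() fixture_network(
  data.frame(source = c("A", "B"), target = c("B", "C"), sign = "+"),
  taxa = c("A", "B", "C"))

test_that("centralities match brute-force values on a directed path", {
  cc <- centralities(path_net())
  rownames(cc) <- cc$taxon
  expect_identical(cc[c("A", "B", "C"), "degree"], c(1L, 2L, 1L))
  expect_equal(cc[c("A", "B", "C"), "betweenness"], c(0, 1, 0))
  # outgoing harmonic closeness, normalized by n-1 = 2:
  # A reaches B at 1, C at 2 -> (1 + 1/2)/2; B reaches C -> 1/2; C -> 0
  expect_equal(cc[c("A", "B", "C"), "closeness"], c(0.75, 0.5, 0))
})

test_that("hubs, isolated nodes and degree bookkeeping behave", {
  star <- fixture_network(
    data.frame(source = "Hub", target = paste0("L", 1:5), sign = "+"),
    taxa = c("Hub", paste0("L", 1:5), "Iso"))
  cc <- centralities(star)
  rownames(cc) <- cc$taxon
  expect_identical(cc["Hub", "degree"], 5L)
  expect_identical(max(cc$degree), cc["Hub", "degree"])
  expect_equal(unlist(cc["Iso", c("degree", "betweenness", "closeness")]),
               c(degree = 0, betweenness = 0, closeness = 0))
  expect_identical(sum(cc$degree), 2L * nrow(star$edges))
})

test_that("rank aggregation places the dominant node first and shares ties densely", {
  cc <- data.frame(taxon = c("Top", "Mid", "Low"),
                   degree = c(9L, 4L, 1L),
                   betweenness = c(8, 3, 0),
                   closeness = c(0.9, 0.5, 0.1))
  rep <- rank_aggregate(cc)
  expect_identical(rep$final_rank[rep$taxon == "Top"], 1L)
  expect_true(rep$key[rep$taxon == "Top"])
  expect_identical(key_microbes(rep), "Top")

  # two co-equal best nodes share final rank 1 (dual key microbes)
  cc2 <- data.frame(taxon = c("K1", "K2", "Rest"),
                    degree = c(5L, 5L, 1L), betweenness = c(2, 2, 0),
                    closeness = c(0.8, 0.8, 0.2))
  rep2 <- rank_aggregate(cc2)
  expect_identical(rep2$final_rank[rep2$taxon %in% c("K1", "K2")], c(1L, 1L))
  expect_identical(sort(key_microbes(rep2)), c("K1", "K2"))
  expect_identical(rep2$final_rank[rep2$taxon == "Rest"], 2L)  # dense

  # relabeling nodes permutes the report identically
  perm <- c(3, 1, 2)
  rep3 <- rank_aggregate(cc[perm, ])
  expect_equal(rep3[order(rep3$taxon), ], rep[order(rep$taxon), ],
               ignore_attr = TRUE)
  # component ranks are permutation-consistent with scores, totals exact
  expect_equal(rep$total_rank,
               rep$rank_degree + rep$rank_betweenness + rep$rank_closeness)
})

test_that("rank_regression is exact on concordant ranks and matches normal equations", {
  cc <- data.frame(taxon = letters[1:6], degree = 6:1,
                   betweenness = as.numeric(6:1), closeness = seq(0.6, 0.1, -0.1))
  rep <- rank_aggregate(cc)
  rr <- suppressMessages(rank_regression(rep))
  expect_equal(rr$r_squared, 1)
  expect_lt(rr$p_value, 1e-6)

  # random rank table vs an independently coded normal-equations oracle
  withr::with_seed(31, {
    rep2 <- data.frame(final_rank = sample(1:8),
                       rank_degree = sample(1:8),
                       rank_closeness = sample(1:8),
                       rank_betweenness = sample(1:8))
    rr2 <- rank_regression(rep2)
    X <- cbind(1, rep2$rank_degree, rep2$rank_closeness, rep2$rank_betweenness)
    y <- rep2$final_rank
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(rr2$r_squared, r2, tolerance = 1e-9)
    expect_true(rr2$r_squared >= 0 && rr2$r_squared <= 1)
  })

  expect_error(rank_regression(rank_aggregate(cc[1:4, ])), ">= 5 nodes")
})

test_that("fragmentation counts weak components", {
  nodes <- c("A", "B", "C")
  complete <- fixture_network(
    expand.grid(source = nodes, target = nodes,
                stringsAsFactors = FALSE) |>
      subset(source != target) |> transform(sign = "+"),
    taxa = nodes)
  expect_identical(fragmentation(complete), 1L)

  none <- fixture_network(data.frame(source = "A", target = "B", sign = "+"),
                          taxa = c("A", "B", paste0("I", 1:4)))
  expect_identical(fragmentation(none), 5L)

  tri <- function(v) data.frame(source = v, target = v[c(2, 3, 1)], sign = "+")
  two_tri <- fixture_network(rbind(tri(c("A", "B", "C")),
                                   tri(c("X", "Y", "Z"))),
                             taxa = c("A", "B", "C", "X", "Y", "Z"))
  expect_identical(fragmentation(two_tri), 2L)
})

test_that("focal_report splits incident edges by direction and sign", {
  net <- fixture_network(
    data.frame(source = c("P1", "P2", "N1", "F", "F", "F"),
               target = c("F", "F", "F", "OutP", "OutN1", "OutN2"),
               sign   = c("+", "+", "-", "+", "-", "-")),
    taxa = c("F", "P1", "P2", "N1", "OutP", "OutN1", "OutN2", "Alone"))
  fr <- focal_report(net, "F")
  expect_identical(fr$influenced_by_positive, c("P1", "P2"))
  expect_identical(fr$influenced_by_negative, "N1")
  expect_identical(fr$influences_positive, "OutP")
  expect_identical(fr$influences_negative, c("OutN1", "OutN2"))
  expect_identical(unname(fr$counts), c(2L, 1L, 1L, 2L))

  lonely <- focal_report(net, "Alone")
  expect_identical(unname(lonely$counts), c(0L, 0L, 0L, 0L))
  expect_identical(unlist(lonely[c("influenced_by_positive",
                                   "influences_negative")],
                          use.names = FALSE), character(0))

  expect_error(focal_report(net, "Ghost"), "available")
  df <- as.data.frame(fr)
  expect_identical(dim(df), c(2L, 4L))
})
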