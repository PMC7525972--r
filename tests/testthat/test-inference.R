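test_that("enumerate_assemblies enumerates lexicographically and subsamples without replacement", {
  full <- enumerate_assemblies(2, 3)
  expected <- rbind(c(1,1,1), c(1,1,2), c(1,2,1), c(1,2,2),
                    c(2,1,1), c(2,1,2), c(2,2,1), c(2,2,2))
  storage.mode(expected) <- "integer"
  expect_identical(unname(full), expected)

  expect_identical(nrow(enumerate_assemblies(1, 7)), 1L)
  expect_error(enumerate_assemblies(3, 11, ceiling = 1e5), "subsample")

  sub <- enumerate_assemblies(3, 11, mode = "subsample", n_subsample = 50,
                              seed = 4)
  expect_identical(dim(sub), c(50L, 11L))
  expect_identical(nrow(unique(sub)), 50L)
  expect_identical(sub, enumerate_assemblies(3, 11, mode = "subsample",
                                             n_subsample = 50, seed = 4))
  expect_message(all8 <- enumerate_assemblies(2, 3, mode = "subsample",
                                              n_subsample = 99, seed = 1),
                 "full enumeration")
  expect_identical(nrow(all8), 8L)
})

test_that("support_threshold_count is the smallest count strictly above cutoff*M", {
  expect_identical(support_threshold_count(177147, 0.7), 124003L)
  expect_identical(support_threshold_count(10, 0.7), 8L)
  expect_identical(support_threshold_count(100, 0.5), 51L)
  expect_identical(support_threshold_count(100, 0.999), 100L)
})

test_that("assemble_series picks the chosen replicate per time point", {
  st <- generate_study(study_design(n_taxa = 5, time_grid = c(0, 1, 2, 4),
                                    seed = 8))
  tab <- st$table
  s1 <- assemble_series(tab, "Sham", c(1, 1, 1, 1))
  rel <- to_relative(tab)
  own <- t(rel[tab$metadata$group == "Sham" & tab$metadata$mouse == 1, ])
  expect_equal(unname(s1), unname(own), ignore_attr = TRUE)
  expect_true(all(abs(colSums(s1) - 1) < 1e-12))

  s2 <- assemble_series(tab, "Sham", c(1, 1, 2, 1))
  differs <- vapply(1:4, function(k) any(s1[, k] != s2[, k]), logical(1))
  expect_identical(differs, c(FALSE, FALSE, TRUE, FALSE))

  expect_error(assemble_series(tab, "Sham", c(1, 1, 4, 1)), "1..3")
  expect_error(assemble_series(tab, "Nope", c(1, 1, 1, 1)), "group")
})

test_that("ols on noiseless discrete-model data recovers the generating parameters", {
  p <- toy_params(seed = 21)
  x0 <- attr(p, "equilibrium") * exp(c(0.4, -0.5, 0.3))
  tg <- 0:11
  tr <- simulate_glv_series(p, x0, tg, noise_sd = 0)
  fit <- fit_glv_series(tr, tg, glv_fit_config("ols"))
  expect_lt(max(abs(fit$interactions - p$interactions)), 1e-6)
  expect_lt(max(abs(fit$growth - p$growth)), 1e-6)
})

test_that("constant series fit to zero coefficients under ols", {
  series <- matrix(c(0.6, 0.4), 2, 5, dimnames = list(c("a", "b"), NULL))
  fit <- suppressWarnings(fit_glv_series(series, 0:4, glv_fit_config("ols")))
  expect_equal(unname(fit$growth), c(0, 0))
  expect_equal(unname(fit$interactions), matrix(0, 2, 2))
})

test_that("pls handles 59 taxa x 11 time points and returns finite coefficients", {
  withr::with_seed(10, {
    series <- matrix(rexp(59 * 11), 59, 11)
    series <- sweep(series, 2, colSums(series), "/")
  })
  fit <- fit_glv_series(series, default_time_grid(),
                        glv_fit_config("pls", n_components = 2))
  expect_true(all(is.finite(fit$interactions)))
  expect_true(all(is.finite(fit$growth)))
  expect_identical(dim(fit$interactions), c(59L, 59L))
})

test_that("fit_glv_series validates its inputs", {
  series <- matrix(1, 2, 3)
  expect_error(fit_glv_series(series, c(0, 0, 1)), "zero time step")
  expect_error(fit_glv_series(series[, 1, drop = FALSE], 0), "2 time points")
  expect_error(fit_glv_series(series, 0:2, glv_fit_config("nope")))
})

test_that("infer_ensemble members equal independent direct fits", {
  st <- generate_study(study_design(n_taxa = 4, replicates_per_group = 2,
                                    time_grid = c(0, 1, 2), seed = 12))
  asm <- enumerate_assemblies(2, 3)
  cfg <- glv_fit_config("ridge", lambda = 0.1)
  ens <- infer_ensemble(st$table, "SNI", asm, cfg)
  expect_identical(dim(ens$a), c(4L, 4L, 8L))
  for (m in seq_len(8)) {
    direct <- fit_glv_series(assemble_series(st$table, "SNI", asm[m, ]),
                             config = cfg)
    expect_equal(ens$a[, , m], direct$interactions)
    expect_equal(ens$b[m, ], direct$growth)
  }
  # permuting the assembly list permutes members identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  ens2 <- infer_ensemble(st$table, "SNI", asm[perm, ], cfg)
  expect_equal(ens2$a, ens$a[, , perm])
})

test_that("consensus_network matches a hand-counted toy ensemble", {
  base <- matrix(0, 3, 3)
  mats <- lapply(1:8, function(m) {
    a <- base
    a[2, 1] <- 1                      # T1 -> T2 positive in 8/8
    a[3, 1] <- if (m <= 5) 1 else -1  # T1 -> T3 positive in 5/8 = 62.5%
    a[1, 3] <- if (m <= 6) -1 else 1  # T3 -> T1 negative in 6/8 = 75%
    diag(a) <- -1                     # self-loops must be excluded
    a
  })
  net <- consensus_network(fake_ensemble(mats), cutoff = 0.7)
  expect_identical(nrow(net$edges), 2L)
  e12 <- net$edges[net$edges$source == "T1" & net$edges$target == "T2", ]
  expect_identical(e12$sign, "+")
  expect_equal(e12$support, 1)
  expect_equal(e12$mean_strength, 1)
  e31 <- net$edges[net$edges$source == "T3" & net$edges$target == "T1", ]
  expect_identical(e31$sign, "-")
  expect_equal(e31$support, 0.75)
  expect_equal(e31$mean_strength, -1)
  expect_false(any(net$edges$source == net$edges$target))
})

test_that("raising the cutoff never adds consensus edges", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      mats <- lapply(1:10, function(m) matrix(rnorm(25), 5, 5))
      ens <- fake_ensemble(mats, taxa = paste0("X", 1:5))
      key <- function(net) paste(net$edges$source, net$edges$target,
                                 net$edges$sign)
      e55 <- key(consensus_network(ens, 0.55))
      e70 <- key(consensus_network(ens, 0.7))
      e90 <- key(consensus_network(ens, 0.9))
      expect_true(all(e70 %in% e55))
      expect_true(all(e90 %in% e70))
    }
  })
})

test_that("a size-1 ensemble's consensus is the dense sign pattern of its fit", {
  withr::with_seed(15, a <- matrix(rnorm(16), 4, 4))
  net <- consensus_network(fake_ensemble(list(a)), cutoff = 0.7)
  off <- which(row(a) != col(a) & a != 0, arr.ind = TRUE)
  expect_identical(nrow(net$edges), nrow(off))
  for (r in seq_len(nrow(off))) {
    i <- off[r, 1]; j <- off[r, 2]
    e <- net$edges[net$edges$source == paste0("T", j) &
                     net$edges$target == paste0("T", i), ]
    expect_identical(e$sign, if (a[i, j] > 0) "+" else "-")
    expect_equal(e$mean_strength, a[i, j])
    expect_equal(e$support, 1)
  }
})

test_that("network edge-list and Gephi exports round-trip / are well-formed", {
  e <- data.frame(source = c("A", "B"), target = c("B", "C"),
                  sign = c("+", "-"))
  net <- fixture_network(e, taxa = c("A", "B", "C", "Lone"))
  f <- tempfile(fileext = ".csv")
  write_network_edges(net, f)
  back <- read_network_edges(f, taxa = net$taxa)
  expect_equal(back$edges, net$edges)

  g <- tempfile(fileext = ".graphml")
  write_network_graphml(net, g)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_identical(as.integer(igraph::vcount(gg)), 4L)
  expect_identical(as.integer(igraph::ecount(gg)), 2L)

  x <- tempfile(fileext = ".gexf")
  write_network_gexf(net, x)
  doc <- xml2::read_xml(x)   # parses => well-formed XML
  expect_identical(length(xml2::xml_find_all(doc, "//*[local-name()='node']")), 4L)
  expect_identical(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 2L)
})
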