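# shared builders for toy objects used across test files

# tiny abundance table with hand-set counts; samples are group x mouse x day
toy_table <- function(counts, groups, mice, days, taxa = NULL) {
  taxa <- taxa %||% paste0("T", seq_len(ncol(counts)))
  ids <- sprintf("s%02d", seq_len(nrow(counts)))
  dimnames(counts) <- list(ids, taxa)
  abundance_table(counts, data.frame(sample = ids, group = groups,
                                     mouse = mice, day = days,
                                     stringsAsFactors = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# wrap a hand-built interaction-coefficient stack (list of n x n matrices)
# into a glv_ensemble so consensus_network can be tested in isolation
fake_ensemble <- function(a_list, taxa = NULL, group = "A") {
  n <- nrow(a_list[[1]])
  taxa <- taxa %||% paste0("T", seq_len(n))
  a <- array(unlist(a_list), c(n, n, length(a_list)),
             dimnames = list(taxa, taxa, NULL))
  structure(list(b = matrix(0, length(a_list), n,
                            dimnames = list(NULL, taxa)),
                 a = a, taxa = taxa,
                 assemblies = matrix(1L, length(a_list), 1),
                 config = glv_fit_config(), group = group),
            class = "glv_ensemble")
}

# consensus_network from a plain edge data.frame (source, target, sign)
fixture_network <- function(edges, taxa = NULL) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(edges, f, row.names = FALSE, quote = FALSE)
  on.exit(unlink(f))
  read_network_edges(f, taxa = taxa)
}

extdata <- function(name) {
  p <- system.file("extdata", name, package = "glvnet")
  if (p == "") p <- file.path("../../inst/extdata", name)
  p
}

# small self-regulating 3-taxon parameter set with informative dynamics
toy_params <- function(seed = 42) {
  generate_interaction_matrix(3, density = 1, strength_scale = 0.05,
                              seed = seed)
}
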