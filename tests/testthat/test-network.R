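test_that("edge threshold is strict and edges carry sign and correlation", {
  # a pair whose control-class Spearman correlation is exactly 0.4:
  # ranks 1..5 vs (4,1,2,3,5) give 1 - 6*12/120 = 0.4
  base <- cbind(a = c(1, 2, 3, 4, 5), b = c(4, 1, 2, 3, 5))
  v <- rbind(base, base)  # cases duplicate the pattern
  rownames(v) <- paste0("s", 1:10)
  cls <- two_class(5, 5)
  expect_identical(nrow(build_network(v, cls, r_threshold = 0.40)), 0L)
  net <- build_network(v, cls, r_threshold = 0.399)
  expect_identical(nrow(net), 2L)  # one edge per class
  expect_equal(net$r, c(0.4, 0.4))
  expect_identical(net$sign, c("positive", "positive"))
  # threshold 1 empties the network even for perfect correlation
  expect_identical(nrow(build_network(v, cls, r_threshold = 1)), 0L)
})

test_that("edge counts are monotone non-increasing in the threshold", {
  sim <- simulate_expression(synth_config(n_molecules = 10, seed = 91))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(th) nrow(build_network(sim$data, r_threshold = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted differential pairs appear in the expected class networks", {
  cfg <- synth_config(n_controls = 500, n_cases = 500, n_molecules = 6,
                      differential_pairs = data.frame(i = 1L, j = 2L,
                                                      rho1 = 0.8, rho2 = -0.2),
                      mean_shift_molecules = data.frame(molecule = integer(),
                                                        effect = numeric()),
                      seed = 92)
  sim <- simulate_expression(cfg)
  net <- build_network(sim$data, r_threshold = 0.40)
  ctl <- net[net$class == "control", ]
  cas <- net[net$class == "case", ]
  expect_true(any(ctl$molecule_a == "mol001" & ctl$molecule_b == "mol002" &
                    ctl$sign == "positive"))
  expect_false(any(cas$molecule_a == "mol001" & cas$molecule_b == "mol002"))
  # restriction to a marker set keeps only those pairs, flagged differential
  net_r <- build_network(sim$data, r_threshold = 0.40,
                         restrict_to = data.frame(molecule_a = "mol001",
                                                  molecule_b = "mol002"))
  expect_true(all(net_r$differential))
  expect_true(all(paste(net_r$molecule_a, net_r$molecule_b) == "mol001 mol002"))
  # hub degrees are computable
  hubs <- network_hubs(net)
  expect_true(all(hubs$degree >= 1))
})

test_that("network exports round-trip through SIF and GraphML", {
  sim <- simulate_expression(synth_config(n_molecules = 6, seed = 93))
  net <- build_network(sim$data, r_threshold = 0.3)
  prefix <- file.path(tempdir(), "net")
  paths <- export_network(net, prefix)
  expect_true(all(file.exists(paths)))
  for (lv in c("control", "case")) {
    e <- net[net$class == lv, ]
    sif <- read_network_sif(paste0(prefix, "_", lv, ".sif"))
    expect_identical(nrow(sif), nrow(e))
    expect_identical(sort(paste(sif$molecule_a, sif$molecule_b)),
                     sort(paste(e$molecule_a, e$molecule_b)))
    expect_identical(sif$sign[order(sif$molecule_a, sif$molecule_b)],
                     e$sign[order(e$molecule_a, e$molecule_b)])
    g <- igraph::read_graph(paste0(prefix, "_", lv, ".graphml"),
                            format = "graphml")
    expect_identical(igraph::ecount(g), as.numeric(nrow(e)))
    expect_equal(sort(igraph::edge_attr(g, "r")), sort(e$r))
  }
  # empty edge set still writes valid empty-graph files
  p2 <- export_network(net[0, ], file.path(tempdir(), "empty"),
                       classes = "control")
  expect_true(all(file.exists(p2)))
  expect_identical(nrow(read_network_sif(grep("sif$", p2, value = TRUE))), 0L)
  g0 <- igraph::read_graph(grep("graphml$", p2, value = TRUE), format = "graphml")
  expect_identical(igraph::ecount(g0), 0)
})
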