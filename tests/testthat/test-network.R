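mk_expr <- function(x) {
  colnames(x) <- c(paste0("D", 1:(ncol(x) / 2)), paste0("C", 1:(ncol(x) / 2)))
  cnc_expr(x, data.frame(sample = colnames(x),
                         group = rep(c("disease", "control"),
                                     each = ncol(x) / 2)))
}

test_that("pearson matches hand computation and clamps rounding", {
  expect_equal(pearson(1:5, 2 * (1:5)), 1)
  expect_equal(pearson(1:5, 5:1), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson(1:5, rep(2, 5)), "constant")
  expect_error(pearson(1:2, 1:2), ">= 3")
})

test_that("duplicate profiles form edges and uncorrelated noise does not", {
  set.seed(50)
  prof <- rnorm(5)
  x <- rbind(l1 = c(prof, rnorm(5)),
             m1 = c(prof + 0.001 * rnorm(5), rnorm(5)),
             m2 = c(rnorm(5), rnorm(5)))
  expr <- mk_expr(x)
  net <- build_cnc_network(expr, "disease", "l1", c("m1", "m2"))
  expect_equal(nrow(net$edges), 1)
  expect_identical(sort(c(net$edges$a, net$edges$b)), c("l1", "m1"))
  expect_gt(net$edges$r, 0.97)
  expect_setequal(net$nodes$id, c("l1", "m1"))  # degree-0 node dropped
})

test_that("edge calls match an exhaustive all-pairs oracle", {
  set.seed(51)
  for (rep in 1:20) {
    n <- 12
    x <- matrix(rnorm(n * 10), n,
                dimnames = list(paste0("g", 1:n), NULL))
    # plant two duplicate pairs
    x[2, 1:5] <- x[1, 1:5]; x[4, 1:5] <- x[3, 1:5]
    expr <- mk_expr(x)
    lnc <- paste0("g", 1:6); mrna <- paste0("g", 7:12)
    net <- build_cnc_network(expr, "disease", lnc, mrna,
                             corr_threshold = 0.9, cnc_only = FALSE)
    ed <- expand.grid(i = 1:n, j = 1:n)
    ed <- ed[ed$i < ed$j, ]
    want <- sum(apply(ed, 1, function(k)
      abs(cor(x[k[1], 1:5], x[k[2], 1:5])) >= 0.9))
    expect_equal(nrow(net$edges), want)
  }
})

test_that("signed thresholding never yields negative edges", {
  set.seed(52)
  prof <- rnorm(5)
  x <- rbind(l1 = c(prof, rnorm(5)),
             m1 = c(-prof, rnorm(5)),
             m2 = c(prof, rnorm(5)))
  expr <- mk_expr(x)
  net_abs <- build_cnc_network(expr, "disease", "l1", c("m1", "m2"))
  expect_setequal(net_abs$edges$sign, c("pos", "neg"))
  net_sgn <- build_cnc_network(expr, "disease", "l1", c("m1", "m2"),
                               use_absolute = FALSE)
  expect_true(all(net_sgn$edges$sign == "pos"))
})

test_that("edges are invariant under sample reordering within a group", {
  set.seed(53)
  x <- matrix(rnorm(80), 8, dimnames = list(paste0("g", 1:8), NULL))
  expr1 <- mk_expr(x)
  perm <- c(5:1, 6:10)
  x2 <- x[, perm]
  expr2 <- cnc_expr(
    `colnames<-`(x2, colnames(expr1$values)[perm]),
    expr1$design[perm, ])
  n1 <- build_cnc_network(expr1, "disease", paste0("g", 1:4),
                          paste0("g", 5:8), corr_threshold = 0.5)
  n2 <- build_cnc_network(expr2, "disease", paste0("g", 1:4),
                          paste0("g", 5:8), corr_threshold = 0.5)
  expect_equal(n1$edges, n2$edges)
})

test_that("cnc_only networks contain no same-biotype edges", {
  set.seed(54)
  prof <- rnorm(5)
  x <- rbind(l1 = c(prof, rnorm(5)), l2 = c(prof, rnorm(5)),
             m1 = c(prof, rnorm(5)))
  expr <- mk_expr(x)
  net <- build_cnc_network(expr, "disease", c("l1", "l2"), "m1")
  pairs <- paste(net$edges$a, net$edges$b)
  expect_false(any(pairs == "l1 l2"))
  expect_setequal(pairs, c("l1 m1", "l2 m1"))
  all_edges <- build_cnc_network(expr, "disease", c("l1", "l2"), "m1",
                                 cnc_only = FALSE)
  expect_equal(nrow(all_edges$edges), 3)
})

test_that("fewer than three samples per group is an error", {
  x <- matrix(rnorm(8), 2, dimnames = list(c("a", "b"), NULL))
  expr <- mk_expr(x)
  expect_error(build_cnc_network(expr, "disease", "a", "b"), ">= 3")
})

toy_net <- function(edges, lnc = character(0)) {
  ids <- sort(unique(c(edges$a, edges$b)))
  edges$r <- rep(1, nrow(edges))
  edges$sign <- rep("pos", nrow(edges))
  structure(list(
    nodes = data.frame(id = ids,
                       biotype = ifelse(ids %in% lnc, "lncRNA", "mRNA"),
                       stringsAsFactors = FALSE),
    edges = edges,
    group = "disease", corr_threshold = 0.97, n_constant = 0L),
    class = "cnc_network")
}

test_that("k-core indices follow the pruning definition on toys", {
  tri <- toy_net(data.frame(a = c("x", "y", "x"), b = c("y", "z", "z")))
  expect_equal(unname(k_core_decomposition(tri)[c("x", "y", "z")]),
               rep(2L, 3))
  tri_pend <- toy_net(data.frame(a = c("x", "y", "x", "w"),
                                 b = c("y", "z", "z", "x")))
  core <- k_core_decomposition(tri_pend)
  expect_equal(unname(core[c("x", "y", "z")]), rep(2L, 3))
  expect_equal(unname(core["w"]), 1L)
})

test_that("k-core matches the iterative-pruning oracle on random graphs", {
  set.seed(55)
  for (rep in 1:25) {
    n <- 30
    ids <- sprintf("n%02d", 1:n)
    pairs <- expand.grid(i = 1:n, j = 1:n)
    pairs <- pairs[pairs$i < pairs$j, ]
    on <- runif(nrow(pairs)) < 0.2
    edges <- data.frame(a = ids[pairs$i[on]], b = ids[pairs$j[on]],
                        stringsAsFactors = FALSE)
    net <- toy_net(edges)
    got <- k_core_decomposition(net)
    want <- oracle_coreness(net$nodes$id, edges$a, edges$b)
    expect_equal(got[net$nodes$id], want[net$nodes$id])
  }
})

test_that("degree bounds the core index", {
  set.seed(56)
  ids <- sprintf("n%02d", 1:20)
  pairs <- expand.grid(i = 1:20, j = 1:20)
  pairs <- pairs[pairs$i < pairs$j, ]
  on <- runif(nrow(pairs)) < 0.15
  net <- toy_net(data.frame(a = ids[pairs$i[on]], b = ids[pairs$j[on]]))
  deg <- node_degrees(net)
  core <- k_core_decomposition(net)
  expect_true(all(deg[names(core)] >= core))
})

test_that("diffK is antisymmetric and zero for identical networks", {
  net1 <- toy_net(data.frame(a = c("x", "y"), b = c("y", "z")))
  net2 <- toy_net(data.frame(a = c("x", "p", "p"), b = c("p", "q", "z")))
  net2$group <- "control"
  st <- diffk(net1, net2)
  net1b <- net1; net1b$group <- "control"
  net2b <- net2; net2b$group <- "disease"
  st_swap <- diffk(net2b, net1b)
  m <- match(st$id, st_swap$id)
  expect_equal(st$diffK, -st_swap$diffK[m])
  net1c <- net1; net1c$group <- "control"
  st_same <- diffk(net1, net1c)
  expect_true(all(st_same$diffK == 0))
})

test_that("a hub present only in disease has diffK 1 and rank 1", {
  hub <- toy_net(data.frame(a = rep("hub", 3), b = c("a", "b", "c")))
  other <- toy_net(data.frame(a = "a", b = "b"))
  other$group <- "control"
  st <- diffk(hub, other)
  expect_identical(st$id[1], "hub")
  expect_equal(st$diffK[1], 1)
  expect_equal(st$K_control[st$id == "hub"], 0)
})

test_that("empty networks produce an empty ranking with a warning", {
  e <- data.frame(a = character(0), b = character(0))
  empty1 <- toy_net(e); empty2 <- toy_net(e); empty2$group <- "control"
  expect_warning(st <- diffk(empty1, empty2), "empty")
  expect_equal(nrow(st), 0)
})

test_that("SIF and GraphML exports round-trip the graph", {
  net <- toy_net(data.frame(a = c("l1", "l1"), b = c("m1", "m2")),
                 lnc = "l1")
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, sif_path = sif, graphml_path = gml)
  expect_identical(readLines(sif), c("l1 pos m1", "l1 pos m2"))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("l1", "m1", "m2"))
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$biotype, c("lncRNA", "mRNA"))
  # empty network still writes a valid document
  e <- toy_net(data.frame(a = character(0), b = character(0)))
  export_network(e, sif_path = sif, graphml_path = gml)
  expect_identical(readLines(sif), character(0))
  g0 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
})
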