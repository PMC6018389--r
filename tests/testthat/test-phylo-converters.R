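# Trees as vertex/edge graphs; Newick and NeXML interchange.

rf_dist <- function(a, b) phangorn::RF.dist(a, b)

test_that("a two-leaf tree with a root edge becomes 3 vertices and 2 edges", {
  g <- newick_to_graph("(A:1.0,B:2.0):0.0;")
  expect_length(g$vertices, 3L)
  expect_length(g$edges, 2L)
  expect_identical(length(g$edges), length(g$vertices) - 1L)
  # deterministic preorder ids
  expect_identical(vapply(g$vertices, `[[`, "", "id"), c("v0", "v1", "v2"))
  expect_identical(vapply(g$edges, `[[`, "", "id"), c("e0", "e1"))
  # branch lengths live on the child vertices; root edge on the root
  bl <- vapply(g$vertices, function(v) v$branch_length %||% NA_real_,
               numeric(1))
  expect_identical(bl, c(0, 1, 2))
})

test_that("a single-leaf tree is one vertex and no edges", {
  g <- newick_to_graph("A;")
  expect_length(g$vertices, 1L)
  expect_length(g$edges, 0L)
  expect_identical(g$vertices[[1L]]$name, "A")
  expect_identical(graph_to_newick(g), "A;")
})

test_that("random trees satisfy tree-ness and invert exactly", {
  set.seed(64)
  phy <- ape::rtree(64, tip.label = paste0("t", 1:64))
  g <- tree_to_graph(phy)
  expect_identical(length(g$edges), length(g$vertices) - 1L)
  back <- graph_to_tree(g)
  expect_identical(rf_dist(phy, back), 0L)
  expect_lt(max(abs(sort(phy$edge.length) - sort(back$edge.length))), 1e-9)
  expect_identical(sort(phy$tip.label), sort(back$tip.label))
})

test_that("tree-ness violations are structural errors naming the vertices", {
  cyc <- list(vertices = list(list(id = "a"), list(id = "b")),
              edges = list(list(id = "e1", source = "a", target = "b"),
                           list(id = "e2", source = "b", target = "a")))
  expect_error(graph_to_tree(cyc), class = "bon_validate_error")
  two_in <- list(
    vertices = list(list(id = "r"), list(id = "x"), list(id = "y"),
                    list(id = "z")),
    edges = list(list(id = "e1", source = "r", target = "x"),
                 list(id = "e2", source = "r", target = "y"),
                 list(id = "e3", source = "x", target = "z"),
                 list(id = "e4", source = "y", target = "z")))
  err <- tryCatch(graph_to_tree(two_in), error = identity)
  expect_s3_class(err, "bon_validate_error")
  expect_match(conditionMessage(err), "z")
  expect_error(graph_to_tree(list(vertices = list(list(id = "a")),
                                  edges = list())),
               class = "bon_validate_error")
  two_roots <- list(
    vertices = list(list(id = "r1"), list(id = "r2"), list(id = "x")),
    edges = list(list(id = "e1", source = "r1", target = "x")))
  err2 <- tryCatch(graph_to_tree(two_roots), error = identity)
  expect_s3_class(err2, "bon_validate_error")
  expect_match(conditionMessage(err2), "r1, r2")
})

test_that("ARG mode admits reticulations but never cycles", {
  retic <- list(
    vertices = list(list(id = "r"), list(id = "x"), list(id = "y"),
                    list(id = "z", name = "recombinant")),
    edges = list(list(id = "e1", source = "r", target = "x"),
                 list(id = "e2", source = "r", target = "y"),
                 list(id = "e3", source = "x", target = "z",
                      breakpoint = 1200L),
                 list(id = "e4", source = "y", target = "z")))
  b <- trees_to_bon(structure(retic, class = "bon_phylo_graph"))
  gs <- bon_to_trees(b, arg = TRUE)
  expect_length(gs, 1L)
  expect_identical(gs[[1L]]$edges[[3L]]$breakpoint, 1200L)
  expect_error(bon_to_trees(b, arg = FALSE), class = "bon_validate_error")
})

test_that("edge metadata round-trips as per-branch annotations", {
  phy <- read_newick("(A:1,(B:2,C:3):4);")
  md <- list(list(rate = 0.12, ci = list(0.08, 0.2)), NULL, NULL, NULL)
  g <- tree_to_graph(phy, edge_metadata = md)
  expect_identical(g$edges[[1L]]$rate, 0.12)
  back <- graph_to_tree(g)
  back_md <- attr(back, "edge_metadata")
  hit <- Filter(Negate(is.null), back_md)
  expect_length(hit, 1L)
  expect_identical(hit[[1L]]$rate, 0.12)
})

test_that("newick io round-trips topologies, lengths and quoted labels", {
  g <- newick_to_graph("(A:1,(B:2,C:3):4);")
  expect_length(g$vertices, 5L)
  expect_length(g$edges, 4L)

  phy <- read_newick("(A,B);")
  expect_identical(sort(phy$tip.label), c("A", "B"))
  expect_identical(read_newick(write_newick(phy))$tip.label, phy$tip.label)

  q <- newick_to_graph("('my taxon':1,B:2);")
  names_q <- vapply(q$vertices, function(v) v$name %||% "", character(1))
  expect_true("my taxon" %in% names_q)
  nwk <- graph_to_newick(q)
  expect_match(nwk, "'my taxon'", fixed = TRUE)
  q2 <- newick_to_graph(nwk)
  expect_true("my taxon" %in%
                vapply(q2$vertices, function(v) v$name %||% "", character(1)))
})

test_that("unbalanced parentheses give a parse error with an offset", {
  err <- tryCatch(read_newick("(A,(B,C);"), error = identity)
  expect_s3_class(err, "bon_parse_error")
  expect_true(is.numeric(err$offset))
  expect_error(read_newick("(A,B));"), class = "bon_parse_error")
})

test_that("property: trees of 10-500 leaves survive graph round-trips", {
  set.seed(17)
  for (n in c(10L, 47L, 123L, 500L)) {
    phy <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    g <- tree_to_graph(phy)
    expect_identical(length(g$edges), length(g$vertices) - 1L)
    back <- graph_to_tree(g)
    expect_identical(rf_dist(phy, back), 0L)
    expect_lt(abs(sum(phy$edge.length) - sum(back$edge.length)), 1e-9)
  }
})

test_that("branch lengths can be emitted on edges instead of vertices", {
  phy <- read_newick("(A:1,(B:2,C:3):4);")
  g <- tree_to_graph(phy, branch_on_edges = TRUE)
  expect_true(all(vapply(g$vertices, function(v)
    is.null(v$branch_length), logical(1))))
  el <- vapply(g$edges, `[[`, numeric(1), "branch_length")
  expect_identical(sort(el), c(1, 2, 3, 4))
  back <- graph_to_tree(g)
  expect_identical(rf_dist(phy, back), 0L)
  expect_identical(sort(back$edge.length), c(1, 2, 3, 4))
})

test_that("trees encode into BON with whole-tree compression", {
  nwk <- gen_trees(5, seed = 9, leaves_range = c(4, 10))
  b <- trees_to_bon(nwk, metadata = lapply(1:5, function(i)
    list(label = sprintf("tree %d", i))))
  expect_identical(b$header$size, 5L)
  expect_identical(b$header$data$tree, 1L)
  s <- bon_serialize(b)
  # metadata beside "tree" stays readable while the tree is compressed
  undecoded <- bon_objects(s, decode = FALSE)
  expect_identical(undecoded[[2L]]$label, "tree 2")
  expect_match(undecoded[[2L]]$tree, "^[A-Za-z0-9+/=]+$")
  # and the compressed value decodes to the identical graph
  gs <- bon_to_trees(s)
  expect_identical(rf_dist(graph_to_tree(gs[[3L]]), read_newick(nwk[3L])), 0L)
})

test_that("NeXML documents convert tree-per-object and round-trip", {
  nwk <- gen_trees(5, seed = 13, leaves_range = c(4, 12))
  nx <- bon_to_nexml(trees_to_bon(nwk))
  b <- nexml_to_bon(nx)
  expect_identical(b$header$size, 5L)
  gs <- bon_to_trees(b)
  for (i in seq_along(nwk)) {
    expect_identical(rf_dist(graph_to_tree(gs[[i]]), read_newick(nwk[i])), 0L)
    expect_lt(abs(sum(graph_to_tree(gs[[i]])$edge.length) -
                    sum(read_newick(nwk[i])$edge.length)), 1e-9)
  }
  expect_error(nexml_to_bon("<nexml></nexml>"), class = "bon_parse_error")
})
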