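test_that("build_graph derives edges from parent references", {
  g <- build_graph(structure_specs(
    c("A", "B", "C"),
    matrix(c("A", "B", "B", "C"), ncol = 2, byrow = TRUE)
  ), name = "chain")
  expect_s3_class(g, "dag_graph")
  expect_setequal(apply(g$edges, 1L, paste, collapse = ">"), c("A>B", "B>C"))
  expect_identical(topological_order(g), c("A", "B", "C"))
})

test_that("coin-toss model has three nodes and two edges into the sequence", {
  g <- coin_toss_graph()
  expect_length(g$nodes, 3L)
  expect_identical(nrow(g$edges), 2L)
  expect_identical(sort(g$edges[, "parent"]), c("n_tosses", "p_heads"))
  expect_identical(unique(g$edges[, "child"]), "sequence")
})

test_that("duplicate names, dangling references and cycles are rejected", {
  expect_error(
    build_graph(list(node("A", const_true), node("A", const_true))),
    class = "simdag_duplicate_name_error")
  expect_error(
    build_graph(list(node("A", const_value, args = list(value = node_ref("Z"))))),
    class = "simdag_unresolved_reference_error")
  err <- tryCatch(build_graph(structure_specs(
    c("A", "B"), matrix(c("A", "B", "B", "A"), ncol = 2, byrow = TRUE)
  )), condition = function(e) e)
  expect_s3_class(err, "simdag_cycle_error")
  expect_match(conditionMessage(err), "A")
  expect_match(conditionMessage(err), "B")
  expect_match(conditionMessage(err), "->")
  # self-loop rejected
  expect_error(
    build_graph(list(node("A", const_value, args = list(value = node_ref("A"))))),
    class = "simdag_cycle_error")
})

test_that("cycle detection agrees with brute-force DFS on all 3-vertex digraphs", {
  pairs3 <- expand.grid(from = 1:3, to = 1:3)
  pairs3 <- as.matrix(pairs3[pairs3$from != pairs3$to, ])
  nm <- c("A", "B", "C")
  for (mask in 0:63) {
    edges_idx <- pairs3[bitwAnd(mask, bitwShiftL(1L, seq_len(6) - 1L)) > 0L, ,
                        drop = FALSE]
    expected_cycle <- dfs_has_cycle(3L, edges_idx)
    edges <- cbind(nm[edges_idx[, 1L]], nm[edges_idx[, 2L]])
    got <- tryCatch({
      build_graph(structure_specs(nm, edges))
      FALSE
    }, simdag_cycle_error = function(e) TRUE)
    expect_identical(got, expected_cycle, info = sprintf("mask %d", mask))
  }
})

test_that("topological order is valid and breaks ties by declaration order", {
  # diamond: the returned order must be one of the valid orders, and the
  # declaration-order tie break must pick A B C D
  nm <- c("A", "B", "C", "D")
  edges <- matrix(c("A", "B", "A", "C", "B", "D", "C", "D"), ncol = 2, byrow = TRUE)
  g <- build_graph(structure_specs(nm, edges))
  valid <- all_topological_orders(nm, edges)
  expect_true(any(vapply(valid, identical, TRUE, topological_order(g))))
  expect_identical(topological_order(g), c("A", "B", "C", "D"))

  # isolated nodes keep declaration order
  iso <- paste0("n", 1:10)
  g2 <- build_graph(structure_specs(iso, matrix(character(0), ncol = 2)))
  expect_identical(topological_order(g2), iso)
})

test_that("topological order respects every edge on random DAGs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:12, 1L)
    nm <- paste0("v", sample(n)) # scrambled names so order isn't alphabetical
    # random DAG: edges only from earlier to later in a hidden permutation
    perm <- sample(n)
    edges <- matrix(character(0), ncol = 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < 0.25)
        edges <- rbind(edges, c(nm[perm[i]], nm[perm[j]]))
    }
    g <- build_graph(structure_specs(nm, edges))
    pos <- match(nm, topological_order(g))
    names(pos) <- nm
    if (nrow(edges) > 0L)
      expect_true(all(pos[edges[, 1L]] < pos[edges[, 2L]]))
    else succeed()
  }
})

test_that("graph building and rendering are pure", {
  nm <- c("A", "B", "C")
  edges <- matrix(c("A", "B", "A", "C"), ncol = 2, byrow = TRUE)
  g1 <- build_graph(structure_specs(nm, edges))
  g2 <- build_graph(structure_specs(nm, edges))
  expect_identical(topological_order(g1), topological_order(g2))
  expect_identical(render_graph(g1), render_graph(g2))
})

test_that("plate expansion replicates nodes with rewired in-plate references", {
  specs <- list(
    node("mu", rand_uniform),
    node("x", rand_normal, args = list(mean = node_ref("mu")),
         plate = list(id = "p", k = 3L)),
    node("y", const_value, args = list(value = node_ref("x")),
         plate = list(id = "p", k = 3L))
  )
  g <- build_graph(specs)
  expect_setequal(names(g$nodes),
                  c("mu", paste0("x_", 1:3), paste0("y_", 1:3)))
  expect_length(g$nodes, 7L) # k*m expanded + shared parent
  # each y_i depends on its own x_i; all x_i on the shared mu
  e <- apply(g$edges, 1L, paste, collapse = ">")
  expect_setequal(e, c("mu>x_1", "mu>x_2", "mu>x_3",
                       "x_1>y_1", "x_2>y_2", "x_3>y_3"))
  # cyclic template stays cyclic after expansion
  bad <- list(
    node("a", const_value, args = list(value = node_ref("b")),
         plate = list(id = "q", k = 2L)),
    node("b", const_value, args = list(value = node_ref("a")),
         plate = list(id = "q", k = 2L))
  )
  expect_error(build_graph(bad), class = "simdag_cycle_error")
  # an unplated node may not reference a plated one
  expect_error(build_graph(list(
    node("a", rand_uniform, plate = 2),
    node("b", const_value, args = list(value = node_ref("a")))
  )), class = "simdag_unresolved_reference_error")
})

test_that("at most one selection and one stratify node are allowed", {
  sel <- function(nm) node(nm, const_true, kind = "selection")
  expect_error(build_graph(list(node("A", const_true), sel("s1"), sel("s2"))),
               class = "simdag_kind_error")
  str <- function(nm) node(nm, function() "a", kind = "stratify")
  expect_error(build_graph(list(node("A", const_true), str("t1"), str("t2"))),
               class = "simdag_kind_error")
})

test_that("render_graph emits one vertex per node and one arc per edge", {
  count <- function(dot, pat) sum(grepl(pat, strsplit(dot, "\n")[[1]]))
  g <- build_graph(structure_specs(c("A", "B"),
                                   matrix(c("A", "B"), ncol = 2)))
  dot <- render_graph(g)
  expect_identical(count(dot, "\\[shape="), 2L)
  expect_identical(count(dot, "->"), 1L)

  dot2 <- render_graph(coin_toss_graph())
  expect_identical(count(dot2, "\\[shape="), 3L)
  expect_identical(count(dot2, "->"), 2L)

  g3 <- build_graph(structure_specs(c("A", "B"), matrix(character(0), ncol = 2)))
  dot3 <- render_graph(g3)
  expect_identical(count(dot3, "\\[shape="), 2L)
  expect_identical(count(dot3, "->"), 0L)

  # node kinds are visually distinguished
  g4 <- build_graph(list(
    node("X", rand_bernoulli),
    node("mask", const_false),
    make_missing_node("Xobs", "X", "mask"),
    node("keep", const_true, kind = "selection"),
    node("grp", function() "a", kind = "stratify")
  ))
  dot4 <- render_graph(g4)
  expect_match(dot4, "shape=diamond")
  expect_match(dot4, "shape=box, style=dashed")
  expect_match(dot4, "shape=octagon")
})

test_that("missing nodes require standard underlying and mask nodes", {
  expect_error(build_graph(list(
    node("keep", const_true, kind = "selection"),
    node("X", rand_uniform),
    make_missing_node("Xobs", "X", "keep")
  )), class = "simdag_kind_error")
  expect_error(build_graph(list(
    node("X", rand_uniform),
    make_missing_node("Xobs", "X", "nope")
  )), class = "simdag_unresolved_reference_error")
})
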