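rad9_rule_text <- '
  tuo:Protein(?rules:someEntity) ^
  tuo:synonym(?rules:someEntity, ?rules:s) ^
  swrlb:containsIgnoreCase(?rules:s, "rad9")
  -> tuo:Rad9(?rules:someEntity)'

interaction_query_text <- '
  tuo:Rad9(?rad9instance) ^
  tuo:plays(?rad9instance, ?participant) ^
  tuo:hasParticipant(?process, ?participant)
  -> sqwrl:select(?rad9instance, ?process)'

test_that("the rule grammar parses rules and select queries", {
  r <- parse_rule(rad9_rule_text)
  expect_s3_class(r, "rbm_rule")
  expect_length(r$antecedent, 3L)
  expect_length(r$consequent, 1L)
  expect_equal(r$consequent[[1]]$pred, "tuo:Rad9")
  expect_equal(r$antecedent[[3]]$kind, "builtin")

  # the conjunction sign and arrow have unicode renderings too
  r2 <- parse_rule(paste0(
    'tuo:Protein(?e) ∧ tuo:synonym(?e, ?s) Λ ',
    'swrlb:containslgnoreCase(?s, "rad9") → tuo:Rad9(?e)'))
  expect_length(r2$antecedent, 3L)

  q <- parse_rule(interaction_query_text)
  expect_s3_class(q, "rbm_select")
  expect_equal(q$projection, c("rad9instance", "process"))

  expect_error(parse_rule("tuo:Protein(?x) -> tuo:Rad9(?y)"),
               "not bound in antecedent")
  expect_error(parse_rule("tuo:p(?x, ?y, ?z) -> tuo:C(?x)"), "arity")
  expect_error(parse_rule('swrlb:noSuchBuiltin(?x, "a") -> tuo:C(?x)'),
               "unregistered builtin")
  expect_error(parse_rule("sqwrl:select(?x) -> tuo:C(?x)"),
               "cannot appear in an antecedent")
  expect_error(parse_rule("tuo:C(?x) -> sqwrl:select(?x) ^ tuo:D(?x)"),
               "single sqwrl:select")
})

test_that("builtins behave as case-insensitive string predicates", {
  expect_true(eval_builtin("containsIgnoreCase",
                           c("RAD9 checkpoint protein", "rad9")))
  expect_false(eval_builtin("containsIgnoreCase", c("RAD53", "rad9")))
  expect_true(eval_builtin("stringEqualIgnoreCase", c("Rad9", "RAD9")))
  expect_true(eval_builtin("contains", c("abcd", "bc")))
  expect_false(eval_builtin("contains", c("ABCD", "bc")))
  expect_error(eval_builtin("nope", c("a", "b")), "unregistered")

  # random text pairs against an independent lowercase-substring oracle
  set.seed(42)
  alphabet <- c(letters, LETTERS, "9", " ")
  for (i in 1:60) {
    a <- paste(sample(alphabet, sample.int(8L, 1L), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample.int(4L, 1L), TRUE), collapse = "")
    expect_identical(eval_builtin("containsIgnoreCase", c(a, b)),
                     oracle_builtin("containsIgnoreCase", list(a, b)),
                     info = paste(a, "/", b))
  }
})

test_that("match agrees with brute-force enumeration on random graphs", {
  antecedents <- list(
    parse_rule("A(?x) -> A(?x)")$antecedent,
    parse_rule("A(?x) ^ op1(?x, ?y) -> A(?x)")$antecedent,
    parse_rule("op1(?x, ?y) ^ dp1(?y, ?v) -> A(?x)")$antecedent,
    parse_rule('B(?x) ^ dp2(?x, ?v) ^ swrlb:containsIgnoreCase(?v, "rad") -> A(?x)')$antecedent,
    parse_rule("op2(?x, ?y) ^ B(?y) ^ op1(?y, ?z) -> A(?x)")$antecedent
  )
  for (seed in 1:5) {
    g <- random_graph(seed)
    for (ante in antecedents) {
      vars <- unique(unlist(lapply(ante, function(a) {
        unlist(lapply(a$args, function(x) if (x$type == "var") x$name))
      })))
      got <- bindings_matrix(match_bindings(g, ante), vars)
      want <- oracle_match(g, ante)
      expect_equal(got, want[, vars, drop = FALSE],
                   info = sprintf("seed %d", seed))
    }
  }
  # a graph with schema but no instances yields no bindings
  schema_only <- instance_graph()
  add_class(schema_only, "A")
  expect_length(match_bindings(schema_only,
                               parse_rule("A(?x) -> A(?x)")$antecedent), 0L)
})

test_that("forward chaining reaches an idempotent, order-independent fixpoint", {
  mk_graph <- function() {
    g <- instance_graph()
    add_class(g, "A"); add_class(g, "B"); add_class(g, "C")
    add_property(g, "p", "object")
    add_instance(g, "t#1", "A", "S")
    add_instance(g, "t#2", "A", "S")
    add_assertion(g, "t#1", "p", "t#2")
    g
  }
  rules <- list(
    parse_rule("B(?x) -> C(?x)", id = "r-late"),
    parse_rule("A(?x) -> B(?x)", id = "r-early"),
    parse_rule("A(?x) ^ p(?x, ?y) -> p(?y, ?x)", id = "r-sym")
  )
  g <- mk_graph()
  rep1 <- apply_rules(g, rules)
  expect_gt(rep1$total_added, 0L)
  snapshot <- write_turtle(g)
  rep2 <- apply_rules(g, rules)           # idempotence
  expect_equal(rep2$total_added, 0L)
  expect_identical(write_turtle(g), snapshot)

  g_perm <- mk_graph()
  apply_rules(g_perm, rules[c(3, 1, 2)])  # order independence
  expect_setequal(instances_of(g_perm, "C"), instances_of(g, "C"))
  expect_identical(sort(strsplit(write_turtle(g_perm), "\n")[[1]]),
                   sort(strsplit(snapshot, "\n")[[1]]))

  # monotonicity: assertions only grow round over round
  expect_equal(assertion_count(g), assertion_count(g_perm))

  # empty rule set leaves the graph untouched
  g2 <- mk_graph()
  rep <- apply_rules(g2, list())
  expect_equal(rep$total_added, 0L)
  expect_identical(write_turtle(g2), write_turtle(mk_graph()))

  # bounded rounds abort with a diagnostic
  expect_error(apply_rules(mk_graph(), rules, max_rounds = 1L), "fixpoint")
})

test_that("guarded individual creation never duplicates individuals", {
  g <- instance_graph()
  add_class(g, "Record"); add_class(g, "Derived")
  add_property(g, "derivedFrom", "object")
  add_instance(g, "t#r1", "Record", "S")
  add_instance(g, "t#r2", "Record", "S")
  rule <- parse_rule(
    "Record(?x) ^ swrlx:makeOWLThing(?new, ?x) -> Derived(?new) ^ derivedFrom(?new, ?x)",
    id = "mk")
  apply_rules(g, list(rule))
  expect_length(instances_of(g, "Derived"), 2L)
  n <- length(g$instances)
  apply_rules(g, list(rule))  # re-running mints nothing new
  expect_length(g$instances, n)
  expect_length(instances_of(g, "Derived"), 2L)
})

test_that("select is de-duplicated, deterministic and never mutates the graph", {
  q <- parse_rule(interaction_query_text)
  expect_equal(nrow(run_select(pipeline_result()$graph, q)), 5L)

  g <- pipeline_result()$graph
  before <- graph_digest(g)
  rows1 <- run_select(g, q)
  rows2 <- run_select(g, q)
  expect_identical(graph_digest(g), before)
  expect_identical(rows1, rows2)
  expect_false(anyDuplicated(rows1) > 0)

  empty <- instance_graph()
  add_class(empty, "tuo:Rad9")
  add_property(empty, "tuo:plays", "object")
  add_property(empty, "tuo:hasParticipant", "object")
  expect_equal(nrow(run_select(empty, q)), 0L)
})

test_that("defined-class classification matches a recursive oracle and composes", {
  defined <- list(
    Dboth = "A and B",
    Dlink = "op1 some B",
    Dnest = "op2 some (op1 some B)"
  )
  for (seed in 1:5) {
    g <- random_graph(seed)
    for (dc in names(defined)) add_class(g, dc)
    want <- oracle_classify(g, defined)
    classify_instances(g, defined)
    for (dc in names(defined)) {
      got <- sort(setdiff(instances_of(g, dc), character()))
      expect_equal(got, want[[dc]], info = sprintf("seed %d class %s", seed, dc))
    }
  }

  # nested defined classes compose through the fixpoint
  g <- instance_graph()
  add_class(g, "Protein"); add_class(g, "Special")
  add_class(g, "Role"); add_class(g, "Process")
  add_class(g, "SpecialRole"); add_class(g, "SpecialProcess")
  add_property(g, "playedBy", "object")
  add_property(g, "hasParticipant", "object")
  add_instance(g, "t#p", c("Protein", "Special"), "S")
  add_instance(g, "t#role", "Role", "S")
  add_instance(g, "t#proc", "Process", "S")
  add_assertion(g, "t#role", "playedBy", "t#p")
  add_assertion(g, "t#proc", "hasParticipant", "t#role")
  rep <- classify_instances(g, list(
    SpecialProcess = "hasParticipant some SpecialRole",
    SpecialRole = "playedBy some Special"
  ))
  expect_equal(instances_of(g, "SpecialProcess"), "t#proc")
  expect_gt(rep$rounds, 1L)

  # a conjunct with no witness fails the whole expression
  g2 <- instance_graph()
  add_class(g2, "A"); add_class(g2, "B"); add_class(g2, "D")
  add_property(g2, "p", "object")
  add_instance(g2, "t#1", "A", "S")
  classify_instances(g2, list(D = "A and (p some B)"))
  expect_length(instances_of(g2, "D"), 0L)
})
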