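# Independent brute-force oracles.  These re-implement the semantics from
# scratch (no shared code with the package internals beyond the public graph
# accessors) so the rule engine, classifier and reconciliation can be
# checked against exhaustive enumeration on small graphs.

oracle_ancestors <- function(g, cls) {
  seen <- cls
  frontier <- cls
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(c) g$classes[[c]]$parents)))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

oracle_is_member <- function(g, id, cls) {
  any(vapply(g$instances[[id]]$classes,
             function(c) cls %in% oracle_ancestors(g, c), logical(1)))
}

oracle_instances_of <- function(g, cls) {
  ids <- names(g$instances)
  ids[vapply(ids, function(id) oracle_is_member(g, id, cls), logical(1))]
}

# domain values for brute-force enumeration: every instance and every
# literal occurring anywhere in the graph
oracle_domain <- function(g) {
  vals <- list()
  for (id in names(g$instances)) {
    vals[[length(vals) + 1L]] <- list(type = "inst", val = id)
  }
  lits <- character()
  for (inst in g$instances) {
    for (a in inst$assertions) {
      if (!is.null(a$value$value)) lits <- c(lits, a$value$value)
    }
  }
  for (v in unique(lits)) {
    vals[[length(vals) + 1L]] <- list(type = "lit", val = v)
  }
  vals
}

oracle_builtin <- function(name, args) {
  a <- args[[1]]; b <- args[[2]]
  switch(name,
    containsIgnoreCase = ,
    containslgnoreCase = {
      # independent route: regexpr on lowered copies
      regexpr(tolower(b), tolower(a), fixed = TRUE) > 0
    },
    contains = regexpr(b, a, fixed = TRUE) > 0,
    equal = a == b,
    stringEqualIgnoreCase = tolower(a) == tolower(b),
    stop("oracle: unknown builtin ", name)
  )
}

oracle_atom_holds <- function(g, atom, env) {
  argval <- function(arg) {
    if (arg$type == "lit") list(type = "lit", val = arg$value) else env[[arg$name]]
  }
  if (atom$kind == "class") {
    v <- argval(atom$args[[1]])
    return(v$type == "inst" && oracle_is_member(g, v$val, atom$pred))
  }
  if (atom$kind == "property") {
    s <- argval(atom$args[[1]]); o <- argval(atom$args[[2]])
    if (s$type != "inst") return(FALSE)
    for (a in g$instances[[s$val]]$assertions) {
      if (a$property != atom$pred) next
      if (!is.null(a$value$ref)) {
        if (o$type == "inst" && a$value$ref == o$val) return(TRUE)
      } else {
        if (o$type == "lit" && a$value$value == o$val) return(TRUE)
      }
    }
    return(FALSE)
  }
  if (atom$kind == "builtin") {
    vals <- lapply(atom$args, argval)
    if (any(vapply(vals, function(v) v$type != "lit", logical(1)))) return(FALSE)
    return(oracle_builtin(atom$local, lapply(vals, `[[`, "val")))
  }
  stop("oracle: unsupported atom kind ", atom$kind)
}

# exhaustive nested-loop join over every assignment of variables to domain
# values; returns a sorted character matrix (one row per solution)
oracle_match <- function(g, antecedent) {
  vars <- unique(unlist(lapply(antecedent, function(a) {
    unlist(lapply(a$args, function(x) if (x$type == "var") x$name))
  })))
  domain <- oracle_domain(g)
  sols <- list()
  recurse <- function(i, env) {
    if (i > length(vars)) {
      if (all(vapply(antecedent, function(a) oracle_atom_holds(g, a, env),
                     logical(1)))) {
        sols[[length(sols) + 1L]] <<- vapply(vars, function(v) env[[v]]$val,
                                             character(1))
      }
      return(invisible(NULL))
    }
    for (d in domain) {
      env[[vars[[i]]]] <- d
      recurse(i + 1L, env)
    }
  }
  recurse(1L, list())
  if (!length(sols)) {
    return(matrix(character(), ncol = length(vars),
                  dimnames = list(NULL, vars)))
  }
  m <- unique(do.call(rbind, sols))
  colnames(m) <- vars
  m[order(apply(m, 1, paste, collapse = "\r")), , drop = FALSE]
}

# render match_bindings() output in the same sorted-matrix form
bindings_matrix <- function(bindings, vars) {
  if (!length(bindings)) {
    return(matrix(character(), ncol = length(vars),
                  dimnames = list(NULL, vars)))
  }
  m <- unique(do.call(rbind, lapply(bindings, function(sol) {
    vapply(vars, function(v) {
      b <- sol[[v]]
      if (b$type == "inst") b$id else b$value
    }, character(1))
  })))
  colnames(m) <- vars
  m[order(apply(m, 1, paste, collapse = "\r")), , drop = FALSE]
}

# independent recursive evaluator for defined classes, iterated to fixpoint
# over an explicit membership table (never touching assert_class)
oracle_classify <- function(g, defined) {
  defined <- lapply(defined, function(e) {
    if (is.character(e)) parse_class_expression(e) else e
  })
  extra <- stats::setNames(vector("list", length(defined)), names(defined))
  for (nm in names(extra)) extra[[nm]] <- character()
  satisfies <- function(id, expr) {
    if (expr$op == "named") {
      if (oracle_is_member(g, id, expr$name)) return(TRUE)
      for (dc in names(extra)) {
        if (id %in% extra[[dc]] && expr$name %in% oracle_ancestors(g, dc)) {
          return(TRUE)
        }
      }
      return(FALSE)
    }
    if (expr$op == "and") {
      return(all(vapply(expr$parts, function(p) satisfies(id, p), logical(1))))
    }
    if (expr$op == "some") {
      for (a in g$instances[[id]]$assertions) {
        if (a$property == expr$property && !is.null(a$value$ref) &&
            satisfies(a$value$ref, expr$filler)) {
          return(TRUE)
        }
      }
      return(FALSE)
    }
    stop("oracle: bad expression")
  }
  repeat {
    changed <- FALSE
    for (dc in names(defined)) {
      for (id in names(g$instances)) {
        if (id %in% extra[[dc]]) next
        if (satisfies(id, defined[[dc]])) {
          extra[[dc]] <- c(extra[[dc]], id)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(extra, sort)
}

# union-find-free partition oracle: connected components of the shared-key
# relation, via igraph
oracle_partition <- function(ids, keys_by_id) {
  edges <- character()
  all_keys <- unique(unlist(keys_by_id))
  for (k in all_keys) {
    grp <- ids[vapply(ids, function(i) k %in% keys_by_id[[i]], logical(1))]
    if (length(grp) > 1L) {
      for (j in 2:length(grp)) edges <- c(edges, grp[[1]], grp[[j]])
    }
  }
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (length(edges)) gr <- gr + igraph::edges(edges)
  comp <- igraph::components(gr)
  split(ids, comp$membership[ids])
}

# small random graphs for property-style tests
random_graph <- function(seed, n_instances = 20L) {
  set.seed(seed)
  g <- instance_graph()
  cls <- c("A", "B", "C", "D", "E")
  for (i in seq_along(cls)) {
    parents <- if (i > 1 && stats::runif(1) < 0.6) {
      sample(cls[seq_len(i - 1L)], 1L)
    } else {
      character()
    }
    add_class(g, cls[[i]], parents)
  }
  add_property(g, "op1", "object")
  add_property(g, "op2", "object")
  add_property(g, "dp1", "data")
  add_property(g, "dp2", "data")
  pool <- c("alpha", "Beta", "GAMMA", "RAD9 checkpoint protein", "rad", "x9")
  n <- sample.int(n_instances, 1L)
  ids <- sprintf("t#i%d", seq_len(n))
  for (i in seq_len(n)) {
    add_instance(g, ids[[i]], sample(cls, sample.int(2L, 1L)), "test")
  }
  for (i in seq_len(n)) {
    for (k in seq_len(sample.int(3L, 1L))) {
      if (stats::runif(1) < 0.5) {
        add_assertion(g, ids[[i]], sample(c("op1", "op2"), 1L),
                      ref(sample(ids, 1L)))
      } else {
        add_assertion(g, ids[[i]], sample(c("dp1", "dp2"), 1L),
                      lit(sample(pool, 1L)))
      }
    }
  }
  g
}

norm_sets <- function(sets) {
  sort(unname(vapply(sets, function(s) paste(sort(s), collapse = "|"),
                     character(1))))
}
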