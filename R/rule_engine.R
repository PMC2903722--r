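# SWRL-like rules and SQWRL-like queries over instance graphs: a plain-text
# rule grammar, builtin predicates, conjunctive matching with subclass
# closure, forward chaining to fixpoint, a non-materializing select, and
# defined-class classification over existential restrictions.
#
# Grammar (one rule per stanza, stanzas separated by blank lines, `#` starts
# a comment):
#
#   tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
#   swrlb:containsIgnoreCase(?s, "rad9") -> tuo:Rad9(?someEntity)
#
# Atoms are `Prefix:Name(arg, ...)` joined by `^` / `∧` / `Λ`, with `->` or
# `→` separating antecedent from consequent.  Variables are `?name` or
# `?prefix:name` (the prefix on a variable is decorative, as in the printed
# form of SWRL rules, and is dropped).  The prefixes `swrlb` (builtins),
# `sqwrl` (select) and `swrlx` (guarded individual creation) are reserved;
# any other prefixed name must resolve to a class (1 argument) or property
# (2 arguments) of the graph the rule is applied to.

# ---------------------------------------------------------------------------
# builtins

.builtins <- new.env(parent = emptyenv())

register_builtin <- function(name, arity, fn) {
  assign(name, list(arity = arity, fn = fn), envir = .builtins)
}

register_builtin("containsIgnoreCase", 2L, function(a, b) {
  grepl(tolower(b), tolower(a), fixed = TRUE)
})
# the printed form of the builtin name occasionally renders the capital I as
# a lowercase l; accept both spellings as the same predicate
register_builtin("containslgnoreCase", 2L, function(a, b) {
  grepl(tolower(b), tolower(a), fixed = TRUE)
})
register_builtin("contains", 2L, function(a, b) grepl(b, a, fixed = TRUE))
register_builtin("equal", 2L, function(a, b) identical(a, b))
register_builtin("stringEqualIgnoreCase", 2L, function(a, b) {
  identical(tolower(a), tolower(b))
})

#' Evaluate a rule builtin predicate
#'
#' Shipped builtins: `containsIgnoreCase`, `contains`, `equal`,
#' `stringEqualIgnoreCase`.  Builtins are pure predicates over literal
#' arguments; unregistered names are rejected at rule parse time.
#'
#' @param name Builtin name (without the `swrlb:` prefix).
#' @param args Character vector of literal arguments.
#' @return Logical scalar.
#' @export
eval_builtin <- function(name, args) {
  if (!exists(name, envir = .builtins, inherits = FALSE)) {
    stop(sprintf("unregistered builtin '%s'", name))
  }
  b <- get(name, envir = .builtins, inherits = FALSE)
  if (length(args) != b$arity) {
    stop(sprintf("builtin '%s' expects %d arguments, got %d", name, b$arity, length(args)))
  }
  isTRUE(do.call(b$fn, as.list(args)))
}

builtin_exists <- function(name) exists(name, envir = .builtins, inherits = FALSE)

# ---------------------------------------------------------------------------
# tokenizer

RBM_TOKEN_PATTERNS <- list(
  c("WS",     "^[\\s ]+"),
  c("AND",    "^(\\^|∧|Λ)"),
  c("ARROW",  "^(->|→)"),
  c("LPAREN", "^\\("),
  c("RPAREN", "^\\)"),
  c("COMMA",  "^,"),
  c("VAR",    "^\\?[A-Za-z][A-Za-z0-9_]*(:[A-Za-z][A-Za-z0-9_]*)?"),
  c("STRING", '^"[^"]*"'),
  c("NAME",   "^[A-Za-z][A-Za-z0-9_]*(-[A-Za-z0-9_]+)*(:[A-Za-z][A-Za-z0-9_]*(-[A-Za-z0-9_]+)*)?"),
  c("NUMBER", "^-?[0-9]+(\\.[0-9]+)?")
)

tokenize_rule_text <- function(text) {
  # strip comments first
  text <- paste(sub("#.*$", "", strsplit(text, "\n", fixed = TRUE)[[1]]),
                collapse = "\n")
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (tp in RBM_TOKEN_PATTERNS) {
      m <- regexpr(tp[2], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (tp[1] != "WS") {
          tokens[[length(tokens) + 1L]] <- list(
            type = tp[1], text = substr(rest, 1L, len), pos = pos
          )
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("rule parse error at position %d: unexpected '%s'",
                   pos, substr(rest, 1L, 10L)))
    }
  }
  tokens
}

# ---------------------------------------------------------------------------
# parser

atom_var_names <- function(atom) {
  vars <- character()
  for (a in atom$args) if (a$type == "var") vars <- c(vars, a$name)
  vars
}

new_token_stream <- function(tokens) {
  s <- new.env(parent = emptyenv())
  s$tokens <- tokens
  s$i <- 1L
  s
}
ts_peek <- function(s) if (s$i <= length(s$tokens)) s$tokens[[s$i]] else NULL
ts_next <- function(s) {
  t <- ts_peek(s)
  if (is.null(t)) stop("rule parse error: unexpected end of input")
  s$i <- s$i + 1L
  t
}
ts_expect <- function(s, type) {
  t <- ts_next(s)
  if (t$type != type) {
    stop(sprintf("rule parse error at position %d: expected %s, got '%s'",
                 t$pos, type, t$text))
  }
  t
}

parse_atom <- function(s) {
  nm <- ts_expect(s, "NAME")
  parts <- strsplit(nm$text, ":", fixed = TRUE)[[1]]
  prefix <- if (length(parts) == 2L) parts[[1]] else ""
  local <- parts[[length(parts)]]
  ts_expect(s, "LPAREN")
  args <- list()
  repeat {
    t <- ts_next(s)
    if (t$type == "VAR") {
      vparts <- strsplit(sub("^\\?", "", t$text), ":", fixed = TRUE)[[1]]
      args[[length(args) + 1L]] <- list(type = "var", name = vparts[[length(vparts)]])
    } else if (t$type == "STRING") {
      args[[length(args) + 1L]] <- list(
        type = "lit", value = substr(t$text, 2L, nchar(t$text) - 1L))
    } else if (t$type == "NUMBER") {
      args[[length(args) + 1L]] <- list(type = "lit", value = t$text)
    } else {
      stop(sprintf("rule parse error at position %d: bad atom argument '%s'",
                   t$pos, t$text))
    }
    t <- ts_next(s)
    if (t$type == "RPAREN") break
    if (t$type != "COMMA") {
      stop(sprintf("rule parse error at position %d: expected ',' or ')'", t$pos))
    }
  }
  kind <- if (prefix == "swrlb") {
    if (!builtin_exists(local)) {
      stop(sprintf("rule parse error at position %d: unregistered builtin '%s'",
                   nm$pos, local))
    }
    b <- get(local, envir = .builtins, inherits = FALSE)
    if (length(args) != b$arity) {
      stop(sprintf("rule parse error at position %d: builtin '%s' expects %d arguments",
                   nm$pos, local, b$arity))
    }
    "builtin"
  } else if (prefix == "sqwrl" && local == "select") {
    if (length(args) < 1L) {
      stop(sprintf("rule parse error at position %d: select needs at least one variable", nm$pos))
    }
    "select"
  } else if (prefix == "swrlx" && local == "makeOWLThing") {
    if (length(args) < 2L) {
      stop(sprintf("rule parse error at position %d: makeOWLThing needs a fresh variable and at least one anchor", nm$pos))
    }
    "make"
  } else if (length(args) == 1L) {
    "class"
  } else if (length(args) == 2L) {
    "property"
  } else {
    stop(sprintf("rule parse error at position %d: atom '%s' has arity %d (classes take 1 argument, properties 2)",
                 nm$pos, nm$text, length(args)))
  }
  list(kind = kind, pred = nm$text, prefix = prefix, local = local, args = args)
}

parse_atom_conjunction <- function(s) {
  atoms <- list(parse_atom(s))
  while (!is.null(ts_peek(s)) && ts_peek(s)$type == "AND") {
    ts_next(s)
    atoms[[length(atoms) + 1L]] <- parse_atom(s)
  }
  atoms
}

#' Parse a rule or select query
#'
#' Parses the package's plain-text rendering of antecedent/consequent rules.
#' A consequent consisting of a `sqwrl:select` atom yields a select query;
#' otherwise the consequent may contain only class and property atoms, every
#' consequent variable must be bound in the antecedent (safety condition),
#' and the antecedent must be non-empty.
#'
#' @param text Rule text (a single rule).
#' @param id Identifier attached to the parsed rule (used in reports and as
#'   the guard key namespace for individual-creating rules).
#' @return An object of class `rbm_rule` or `rbm_select`.
#' @export
parse_rule <- function(text, id = "rule") {
  s <- new_token_stream(tokenize_rule_text(text))
  antecedent <- parse_atom_conjunction(s)
  ts_expect(s, "ARROW")
  consequent <- parse_atom_conjunction(s)
  trailing <- ts_peek(s)
  if (!is.null(trailing)) {
    stop(sprintf("rule parse error at position %d: trailing input '%s'",
                 trailing$pos, trailing$text))
  }
  if (!length(antecedent)) stop("rule parse error: empty antecedent")
  ante_vars <- unique(unlist(lapply(antecedent, atom_var_names)))
  bad_kind <- vapply(antecedent, function(a) a$kind == "select", logical(1))
  if (any(bad_kind)) stop("rule parse error: sqwrl:select cannot appear in an antecedent")
  is_select <- any(vapply(consequent, function(a) a$kind == "select", logical(1)))
  if (is_select) {
    if (length(consequent) != 1L) {
      stop("rule parse error: a select consequent must be a single sqwrl:select atom")
    }
    proj <- atom_var_names(consequent[[1]])
    unbound <- setdiff(proj, ante_vars)
    if (length(unbound)) {
      stop(sprintf("rule parse error: projection variable(s) not bound in antecedent: %s",
                   paste(unbound, collapse = ", ")))
    }
    return(structure(list(id = id, antecedent = antecedent, projection = proj),
                     class = "rbm_select"))
  }
  for (a in consequent) {
    if (!a$kind %in% c("class", "property")) {
      stop(sprintf("rule parse error: consequent atom '%s' must be a class or property atom",
                   a$pred))
    }
  }
  cons_vars <- unique(unlist(lapply(consequent, atom_var_names)))
  unbound <- setdiff(cons_vars, ante_vars)
  if (length(unbound)) {
    stop(sprintf("rule parse error: consequent variable(s) not bound in antecedent: %s",
                 paste(unbound, collapse = ", ")))
  }
  structure(list(id = id, antecedent = antecedent, consequent = consequent),
            class = "rbm_rule")
}

#' Parse a rule file
#'
#' A rule file is UTF-8 text with one rule per stanza (stanzas separated by
#' blank lines) and `#` comments.
#'
#' @param path File path.
#' @param label Label used to build rule ids (`<label>:<index>`); defaults to
#'   the file name.
#' @return A list of `rbm_rule` / `rbm_select` objects.
#' @export
parse_rules_file <- function(path, label = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  blank <- !nzchar(trimws(lines))
  stanzas <- split(lines[!blank], cumsum(blank)[!blank])
  stanzas <- Filter(function(x) nzchar(trimws(paste(x, collapse = " "))), stanzas)
  out <- vector("list", length(stanzas))
  for (i in seq_along(stanzas)) {
    out[[i]] <- parse_rule(paste(stanzas[[i]], collapse = "\n"),
                           id = sprintf("%s:%d", label, i))
  }
  out
}

# ---------------------------------------------------------------------------
# matching

binding_inst <- function(id) list(type = "inst", id = id)
binding_lit <- function(value) list(type = "lit", value = value)

binding_text <- function(v) if (v$type == "inst") v$id else v$value

# convert an assertion value into a binding value
assertion_binding_value <- function(v) {
  if (is_ref(v)) binding_inst(v$ref) else binding_lit(v$value)
}

resolve_class_atom <- function(graph, atom) {
  if (is.null(graph$classes[[atom$pred]])) {
    if (!is.null(graph$properties[[atom$pred]])) {
      stop(sprintf("atom '%s' has 1 argument but names a property", atom$pred))
    }
    stop(sprintf("unknown class '%s' in rule atom", atom$pred))
  }
  atom$pred
}

resolve_property_atom <- function(graph, atom) {
  pdef <- graph$properties[[atom$pred]]
  if (is.null(pdef)) {
    if (!is.null(graph$classes[[atom$pred]])) {
      stop(sprintf("atom '%s' has 2 arguments but names a class", atom$pred))
    }
    stop(sprintf("unknown property '%s' in rule atom", atom$pred))
  }
  pdef
}

expand_class_atom <- function(graph, solutions, atom) {
  cls <- resolve_class_atom(graph, atom)
  members <- instances_of(graph, cls)
  arg <- atom$args[[1]]
  out <- list()
  for (sol in solutions) {
    if (arg$type == "var" && !is.null(sol[[arg$name]])) {
      v <- sol[[arg$name]]
      if (v$type == "inst" && v$id %in% members) out[[length(out) + 1L]] <- sol
    } else if (arg$type == "var") {
      for (m in members) {
        s2 <- sol
        s2[[arg$name]] <- binding_inst(m)
        out[[length(out) + 1L]] <- s2
      }
    } else {
      if (arg$value %in% members) out[[length(out) + 1L]] <- sol
    }
  }
  out
}

expand_property_atom <- function(graph, solutions, atom) {
  pdef <- resolve_property_atom(graph, atom)
  pairs <- list()
  for (inst in graph$instances) {
    for (a in inst$assertions) {
      if (a$property == atom$pred) {
        pairs[[length(pairs) + 1L]] <-
          list(s = binding_inst(inst$id), o = assertion_binding_value(a$value))
      }
    }
  }
  sarg <- atom$args[[1]]
  oarg <- atom$args[[2]]
  arg_matches <- function(arg, sol, val) {
    if (arg$type == "lit") {
      return(val$type == "lit" && identical(val$value, arg$value) ||
               val$type == "inst" && identical(val$id, arg$value))
    }
    b <- sol[[arg$name]]
    if (is.null(b)) return(NA)  # unbound: will extend
    identical(binding_text(b), binding_text(val)) && identical(b$type, val$type)
  }
  out <- list()
  for (sol in solutions) {
    for (p in pairs) {
      ms <- arg_matches(sarg, sol, p$s)
      mo <- arg_matches(oarg, sol, p$o)
      if (isFALSE(ms) || isFALSE(mo)) next
      s2 <- sol
      if (is.na(ms)) s2[[sarg$name]] <- p$s
      if (is.na(mo)) s2[[oarg$name]] <- p$o
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

filter_builtin_atom <- function(solutions, atom) {
  out <- list()
  for (sol in solutions) {
    args <- character(length(atom$args))
    ok <- TRUE
    for (i in seq_along(atom$args)) {
      a <- atom$args[[i]]
      if (a$type == "lit") {
        args[[i]] <- a$value
      } else {
        b <- sol[[a$name]]
        if (is.null(b)) stop(sprintf("builtin '%s' evaluated with unbound variable '?%s'",
                                     atom$local, a$name))
        args[[i]] <- binding_text(b)
      }
    }
    if (ok && eval_builtin(atom$local, args)) out[[length(out) + 1L]] <- sol
  }
  out
}

atom_is_ready <- function(atom, bound_vars) {
  if (atom$kind %in% c("class", "property")) return(TRUE)
  if (atom$kind == "builtin") {
    return(all(atom_var_names(atom) %in% bound_vars))
  }
  if (atom$kind == "make") {
    anchor_vars <- unlist(lapply(atom$args[-1], function(a) if (a$type == "var") a$name))
    return(all(anchor_vars %in% bound_vars))
  }
  FALSE
}

expand_make_atom <- function(graph, solutions, atom, rule_id) {
  # guarded individual creation: the fresh variable binds to an id derived
  # from (rule id, anchor values); an individual already minted for that key
  # is reused, so re-running the rule never duplicates individuals
  fresh <- atom$args[[1]]
  if (fresh$type != "var") stop("makeOWLThing: first argument must be a variable")
  out <- list()
  for (sol in solutions) {
    anchors <- vapply(atom$args[-1], function(a) {
      if (a$type == "lit") a$value else binding_text(sol[[a$name]])
    }, character(1))
    new_id <- sprintf("new#%s|%s", rule_id, paste(anchors, collapse = "|"))
    if (!has_instance(graph, new_id)) {
      add_instance(graph, new_id, character(), source = "rule")
    }
    s2 <- sol
    s2[[fresh$name]] <- binding_inst(new_id)
    out[[length(out) + 1L]] <- s2
  }
  out
}

#' Match an antecedent against a graph
#'
#' Returns every variable binding that satisfies all atoms conjunctively.
#' Class atoms honor subclass closure; builtin atoms are evaluated once all
#' their variables are bound.  Binding order is deterministic (graph
#' insertion order drives enumeration).
#'
#' @param graph An `InstanceGraph`.
#' @param antecedent A list of atoms (e.g. `rule$antecedent`).
#' @param rule_id Rule identifier, used only when the antecedent contains a
#'   guarded `swrlx:makeOWLThing` atom.
#' @return A list of bindings; each binding is a named list mapping variable
#'   names to values of the form `list(type = "inst", id = ...)` or
#'   `list(type = "lit", value = ...)`.
#' @export
match_bindings <- function(graph, antecedent, rule_id = "query") {
  solutions <- list(stats::setNames(list(), character()))
  pending <- antecedent
  bound <- character()
  while (length(pending)) {
    idx <- NULL
    for (i in seq_along(pending)) {
      if (atom_is_ready(pending[[i]], bound)) { idx <- i; break }
    }
    if (is.null(idx)) {
      stop(sprintf("rule '%s': builtin/makeOWLThing arguments are never bound by any class or property atom",
                   rule_id))
    }
    atom <- pending[[idx]]
    pending <- pending[-idx]
    solutions <- switch(atom$kind,
      class    = expand_class_atom(graph, solutions, atom),
      property = expand_property_atom(graph, solutions, atom),
      builtin  = filter_builtin_atom(solutions, atom),
      make     = expand_make_atom(graph, solutions, atom, rule_id)
    )
    bound <- unique(c(bound, atom_var_names(atom)))
    if (!length(solutions)) return(list())
  }
  solutions
}

# ---------------------------------------------------------------------------
# forward chaining

assert_consequent <- function(graph, atom, sol) {
  added <- 0L
  if (atom$kind == "class") {
    arg <- atom$args[[1]]
    id <- if (arg$type == "var") sol[[arg$name]]$id else arg$value
    if (is.null(graph$classes[[atom$pred]])) {
      stop(sprintf("unknown class '%s' in rule consequent", atom$pred))
    }
    if (assert_class(graph, id, atom$pred)) added <- added + 1L
  } else {
    pdef <- resolve_property_atom(graph, atom)
    subj_arg <- atom$args[[1]]
    obj_arg <- atom$args[[2]]
    subj <- if (subj_arg$type == "var") sol[[subj_arg$name]]$id else subj_arg$value
    value <- if (obj_arg$type == "lit") {
      if (pdef$kind == "object") ref(obj_arg$value) else lit(obj_arg$value)
    } else {
      b <- sol[[obj_arg$name]]
      if (b$type == "inst") {
        if (pdef$kind == "data") lit(b$id) else ref(b$id)
      } else {
        if (pdef$kind == "object") {
          stop(sprintf("object property '%s' in consequent bound to a literal", atom$pred))
        }
        lit(b$value)
      }
    }
    if (add_assertion(graph, subj, atom$pred, value)) added <- added + 1L
  }
  added
}

#' Apply rules by forward chaining to fixpoint
#'
#' Runs rounds of match-and-assert until a round adds no new class membership
#' or property assertion.  Assertions have set semantics, so re-running is
#' idempotent, and individual-creating (`swrlx:makeOWLThing`) antecedents are
#' guarded by a (rule id, anchor binding) key so no duplicate individuals are
#' ever minted.  The assertion set only grows (no retraction), hence the
#' fixpoint is independent of rule order.
#'
#' @param graph An `InstanceGraph`, mutated in place.
#' @param rules A list of `rbm_rule` objects (select queries are rejected).
#' @param max_rounds Abort with a diagnostic if the fixpoint is not reached
#'   within this many rounds.
#' @return A report: `list(rounds, total_added, by_rule)` where `by_rule`
#'   maps rule ids to the number of assertions they added.
#' @export
apply_rules <- function(graph, rules, max_rounds = 100L) {
  for (r in rules) {
    if (inherits(r, "rbm_select")) {
      stop(sprintf("'%s' is a select query; use run_select()", r$id))
    }
    stopifnot(inherits(r, "rbm_rule"))
  }
  by_rule <- stats::setNames(integer(length(rules)),
                             vapply(rules, `[[`, character(1), "id"))
  total <- 0L
  rounds <- 0L
  repeat {
    round_added <- 0L
    for (r in rules) {
      sols <- match_bindings(graph, r$antecedent, rule_id = r$id)
      for (sol in sols) {
        for (atom in r$consequent) {
          n <- assert_consequent(graph, atom, sol)
          round_added <- round_added + n
          by_rule[[r$id]] <- by_rule[[r$id]] + n
        }
      }
    }
    total <- total + round_added
    rounds <- rounds + 1L
    if (round_added == 0L) break
    if (rounds >= max_rounds) {
      stop(sprintf("forward chaining did not reach a fixpoint within %d rounds (%d assertions added so far)",
                   max_rounds, total))
    }
  }
  list(rounds = rounds, total_added = total, by_rule = as.list(by_rule))
}

#' Run a select query (non-materializing)
#'
#' Evaluates the query's antecedent and returns the projected bindings as a
#' data frame.  The graph is bit-identical before and after: select results
#' are presented, never stored back into the ontology.  Rows are
#' deterministic and de-duplicated.
#'
#' @param graph An `InstanceGraph`.
#' @param query An `rbm_select` object.
#' @return A data frame with one column per projection variable; instance
#'   bindings render as ids, literal bindings as their text.
#' @export
run_select <- function(graph, query) {
  stopifnot(inherits(query, "rbm_select"))
  sols <- match_bindings(graph, query$antecedent, rule_id = query$id)
  cols <- lapply(query$projection, function(v) {
    vapply(sols, function(sol) binding_text(sol[[v]]), character(1))
  })
  df <- as.data.frame(stats::setNames(cols, query$projection),
                      stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) {
    return(df)
  }
  unique(df)
}

# ---------------------------------------------------------------------------
# class expressions and defined-class classification

#' Class expression constructors
#'
#' Class expressions are the classifier's input: a named class, an
#' intersection, or an existential restriction (`property some filler`).
#'
#' @param name Class identifier.
#' @param ... Sub-expressions of an intersection.
#' @param property Object property identifier.
#' @param filler Sub-expression.
#' @return A `ClassExpression` object.
#' @export
ce_named <- function(name) {
  structure(list(op = "named", name = name), class = "ClassExpression")
}

#' @rdname ce_named
#' @export
ce_and <- function(...) {
  structure(list(op = "and", parts = list(...)), class = "ClassExpression")
}

#' @rdname ce_named
#' @export
ce_some <- function(property, filler) {
  if (is.character(filler)) filler <- ce_named(filler)
  structure(list(op = "some", property = property, filler = filler),
            class = "ClassExpression")
}

#' Parse a class expression
#'
#' Manchester-style textual syntax: `Name`, `A and B`, `prop some Expr`,
#' parenthesized grouping.  Example:
#' `tuo:hasParticipant some (tuo:playedBy some tuo:Rad9)`.
#'
#' @param text Expression text.
#' @return A `ClassExpression`.
#' @export
parse_class_expression <- function(text) {
  s <- new_token_stream(tokenize_rule_text(text))
  expr <- parse_ce_conj(s)
  trailing <- ts_peek(s)
  if (!is.null(trailing)) {
    stop(sprintf("class expression parse error at position %d: trailing '%s'",
                 trailing$pos, trailing$text))
  }
  expr
}

parse_ce_conj <- function(s) {
  parts <- list(parse_ce_primary(s))
  while (!is.null(ts_peek(s)) && ts_peek(s)$type == "NAME" &&
         ts_peek(s)$text == "and") {
    ts_next(s)
    parts[[length(parts) + 1L]] <- parse_ce_primary(s)
  }
  if (length(parts) == 1L) parts[[1]] else do.call(ce_and, parts)
}

parse_ce_primary <- function(s) {
  t <- ts_peek(s)
  if (is.null(t)) stop("class expression parse error: unexpected end of input")
  if (t$type == "LPAREN") {
    ts_next(s)
    inner <- parse_ce_conj(s)
    ts_expect(s, "RPAREN")
    return(inner)
  }
  nm <- ts_expect(s, "NAME")
  nxt <- ts_peek(s)
  if (!is.null(nxt) && nxt$type == "NAME" && nxt$text == "some") {
    ts_next(s)
    filler <- parse_ce_primary(s)
    return(ce_some(nm$text, filler))
  }
  ce_named(nm$text)
}

instance_satisfies <- function(graph, id, expr) {
  switch(expr$op,
    named = {
      inst <- graph$instances[[id]]
      any(vapply(inst$classes, function(cls) {
        expr$name %in% class_ancestors(graph, cls)
      }, logical(1)))
    },
    and = all(vapply(expr$parts, function(p) instance_satisfies(graph, id, p),
                     logical(1))),
    some = {
      vals <- assertion_values(graph, id, expr$property)
      any(vapply(vals, function(v) {
        has_instance(graph, v) && instance_satisfies(graph, v, expr$filler)
      }, logical(1)))
    },
    stop(sprintf("unknown class expression op '%s'", expr$op))
  )
}

#' Classify instances into defined classes
#'
#' Each instance satisfying a defined class's expression gains (asserted)
#' membership in that class.  Evaluation of existential restrictions follows
#' object-property assertions; classification is iterated to fixpoint so that
#' nested defined classes compose.
#'
#' @param graph An `InstanceGraph`, mutated in place.
#' @param defined Named list mapping defined-class identifiers to
#'   `ClassExpression` objects (or expression text, parsed on the fly).  The
#'   class identifiers must exist in the graph.
#' @param max_rounds Abort with a diagnostic if membership does not stabilize
#'   within this many rounds.
#' @return A report: `list(rounds, added, members)` with `members` mapping
#'   each defined class to its (possibly empty) member id vector.
#' @export
classify_instances <- function(graph, defined, max_rounds = 100L) {
  defined <- lapply(defined, function(e) {
    if (is.character(e)) parse_class_expression(e) else e
  })
  for (dc in names(defined)) {
    if (is.null(graph$classes[[dc]])) {
      stop(sprintf("defined class '%s' is not declared in the graph", dc))
    }
  }
  # resolve filler fixpoint within the evaluation above
  added <- 0L
  rounds <- 0L
  repeat {
    round_added <- 0L
    for (dc in names(defined)) {
      for (id in names(graph$instances)) {
        inst <- graph$instances[[id]]
        if (dc %in% inst$classes) next
        if (instance_satisfies(graph, id, defined[[dc]])) {
          assert_class(graph, id, dc)
          round_added <- round_added + 1L
        }
      }
    }
    added <- added + round_added
    rounds <- rounds + 1L
    if (round_added == 0L) break
    if (rounds >= max_rounds) {
      stop(sprintf("defined-class classification did not stabilize within %d rounds",
                   max_rounds))
    }
  }
  members <- lapply(stats::setNames(names(defined), names(defined)),
                    function(dc) instances_of(graph, dc))
  list(rounds = rounds, added = added, members = members)
}
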