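# Reader and writer for BEL Script documents (BEL 2.0 subset).
#
# Supported term functions: p(), g(), r(), m(), a(), complex(), bp(),
# path(), rxn() (opaque), act() (wrapper), pmod(), var(). Relations may be
# written as keywords (increases, directlyIncreases, ...) or the usual
# arrow forms (->, =>, -|, =|, --). SET/UNSET annotation blocks, DOCUMENT
# metadata and DEFINE NAMESPACE declarations are honoured. Unparseable
# lines are reported with line numbers, never silently dropped.

# ---- term-level recursive-descent parser -----------------------------------

new_cursor <- function(text) {
  env <- new.env(parent = emptyenv())
  env$s <- strsplit(text, "", fixed = TRUE)[[1]]
  env$i <- 1L
  env$n <- length(env$s)
  env
}

cur_peek <- function(cur) if (cur$i <= cur$n) cur$s[cur$i] else ""

cur_skip_ws <- function(cur) {
  while (cur$i <= cur$n && cur$s[cur$i] %in% c(" ", "\t")) cur$i <- cur$i + 1L
}

cur_fail <- function(cur, msg) {
  stop(structure(
    class = c("bel_parse_error", "error", "condition"),
    list(message = msg, call = NULL, column = cur$i)
  ))
}

cur_expect <- function(cur, ch) {
  if (cur_peek(cur) != ch) cur_fail(cur, sprintf("expected '%s'", ch))
  cur$i <- cur$i + 1L
}

# bare name: letters, digits, _ . -
cur_name <- function(cur) {
  start <- cur$i
  while (cur$i <= cur$n && grepl("[A-Za-z0-9_.-]", cur$s[cur$i])) cur$i <- cur$i + 1L
  if (cur$i == start) cur_fail(cur, "expected a name")
  paste(cur$s[start:(cur$i - 1L)], collapse = "")
}

# double-quoted string with backslash escapes
cur_string <- function(cur) {
  cur_expect(cur, '"')
  out <- character(0)
  while (cur$i <= cur$n) {
    ch <- cur$s[cur$i]
    if (ch == "\\") {
      if (cur$i + 1L > cur$n) cur_fail(cur, "dangling escape")
      out <- c(out, cur$s[cur$i + 1L])
      cur$i <- cur$i + 2L
    } else if (ch == '"') {
      cur$i <- cur$i + 1L
      return(paste(out, collapse = ""))
    } else {
      out <- c(out, ch)
      cur$i <- cur$i + 1L
    }
  }
  cur_fail(cur, "unterminated string")
}

# NAME ':' (NAME | STRING) -> c(namespace, identifier)
cur_nsarg <- function(cur, prefix = NULL) {
  ns <- prefix %||% cur_name(cur)
  cur_expect(cur, ":")
  id <- if (cur_peek(cur) == '"') cur_string(cur) else cur_name(cur)
  c(ns, id)
}

parse_pmod_args <- function(cur) {
  cur_expect(cur, "(")
  cur_skip_ws(cur)
  code <- cur_name(cur)
  residue <- NULL
  position <- NULL
  cur_skip_ws(cur)
  if (cur_peek(cur) == ",") {
    cur$i <- cur$i + 1L
    cur_skip_ws(cur)
    residue <- cur_name(cur)
    cur_skip_ws(cur)
    if (cur_peek(cur) == ",") {
      cur$i <- cur$i + 1L
      cur_skip_ws(cur)
      position <- suppressWarnings(as.integer(cur_name(cur)))
      if (is.na(position)) cur_fail(cur, "pmod position must be an integer")
      cur_skip_ws(cur)
    }
  }
  cur_expect(cur, ")")
  mod_type <- switch(code, Ph = "phosphorylation", Ub = "ubiquitination", "other_ptm")
  bel_modification(mod_type, residue = residue, position = position, code = code)
}

parse_var_args <- function(cur) {
  cur_expect(cur, "(")
  cur_skip_ws(cur)
  desc <- if (cur_peek(cur) == '"') cur_string(cur) else cur_name(cur)
  cur_skip_ws(cur)
  cur_expect(cur, ")")
  bel_modification("sequence_variant", residue = desc)
}

# Parse one term. Returns list(entity = bel_entity, activity = logical).
cur_term <- function(cur) {
  cur_skip_ws(cur)
  fn <- cur_name(cur)
  if (fn == "act") {
    cur_expect(cur, "(")
    inner <- cur_term(cur)
    cur_skip_ws(cur)
    cur_expect(cur, ")")
    if (inner$activity) cur_fail(cur, "nested act() is not allowed")
    return(list(entity = inner$entity, activity = TRUE))
  }
  if (!fn %in% names(FUNC_TO_CLASS)) {
    cur_fail(cur, sprintf("unknown BEL function '%s'", fn))
  }
  klass <- unname(FUNC_TO_CLASS[fn])
  cur_expect(cur, "(")
  cur_skip_ws(cur)

  if (klass == "complex") {
    # composed complex: complex(p(..), p(..), ...) vs named complex(FPLX:..)
    save <- cur$i
    nm <- tryCatch(cur_name(cur), error = function(e) NULL)
    if (!is.null(nm) && cur_peek(cur) == "(") {
      # composed: rewind and read member terms
      cur$i <- save
      members <- list()
      repeat {
        m <- cur_term(cur)
        if (m$activity) cur_fail(cur, "act() not allowed inside complex()")
        members <- c(members, list(m$entity))
        cur_skip_ws(cur)
        if (cur_peek(cur) == ",") { cur$i <- cur$i + 1L; cur_skip_ws(cur) } else break
      }
      cur_expect(cur, ")")
      ent <- bel_entity("complex", members = members)
      return(list(entity = ent, activity = FALSE))
    }
    cur$i <- save
  }

  ns <- cur_nsarg(cur)
  variants <- list()
  cur_skip_ws(cur)
  while (cur_peek(cur) == ",") {
    cur$i <- cur$i + 1L
    cur_skip_ws(cur)
    sub_fn <- cur_name(cur)
    if (sub_fn == "pmod") {
      variants <- c(variants, list(parse_pmod_args(cur)))
    } else if (sub_fn == "var") {
      variants <- c(variants, list(parse_var_args(cur)))
    } else {
      cur_fail(cur, sprintf("unsupported term argument '%s'", sub_fn))
    }
    cur_skip_ws(cur)
  }
  cur_expect(cur, ")")
  ungrounded <- identical(ns[1], "TEXT")
  ent <- if (ungrounded) {
    bel_entity(klass, label = ns[2])
  } else {
    bel_entity(klass, namespace = ns[1], identifier = ns[2], variants = variants)
  }
  if (!ungrounded && length(variants) &&
      !klass %in% c("gene", "rna", "protein")) {
    cur_fail(cur, sprintf("variants not permitted on %s terms", klass))
  }
  list(entity = ent, activity = FALSE)
}

#' Parse a single BEL term
#'
#' @param text a BEL term string, e.g. `"p(HGNC:MAPT, pmod(Ph, Ser, 396))"`
#' @return a [bel_entity()]; the attribute `activity` records an `act()`
#'   wrapper
#' @export
parse_bel_term <- function(text) {
  cur <- new_cursor(trimws(text))
  res <- cur_term(cur)
  cur_skip_ws(cur)
  if (cur$i <= cur$n) cur_fail(cur, "trailing characters after term")
  out <- res$entity
  attr(out, "activity") <- res$activity
  out
}

#' Parse a single BEL statement line
#'
#' @param text `"<subject term> <relation> <object term>"`
#' @return list with `subject`, `object` ([bel_entity()]), `relation`,
#'   `subject_activity`, `object_activity`
#' @export
parse_bel_statement <- function(text) {
  cur <- new_cursor(trimws(text))
  subj <- cur_term(cur)
  cur_skip_ws(cur)
  # relation token: keyword or arrow symbol
  start <- cur$i
  while (cur$i <= cur$n && !cur$s[cur$i] %in% c(" ", "\t")) cur$i <- cur$i + 1L
  if (cur$i == start) cur_fail(cur, "missing relation")
  token <- paste(cur$s[start:(cur$i - 1L)], collapse = "")
  if (!token %in% names(KEYWORD_TO_REL)) {
    cur$i <- start
    cur_fail(cur, sprintf("unknown relation keyword '%s'", token))
  }
  relation <- unname(KEYWORD_TO_REL[token])
  obj <- cur_term(cur)
  cur_skip_ws(cur)
  if (cur$i <= cur$n) cur_fail(cur, "trailing characters after statement")
  list(
    subject = subj$entity, object = obj$entity, relation = relation,
    subject_activity = subj$activity, object_activity = obj$activity
  )
}

# ---- document-level reader -------------------------------------------------

unquote_value <- function(v) {
  v <- trimws(v)
  if (startsWith(v, '"')) {
    cur <- new_cursor(v)
    cur_string(cur)
  } else if (startsWith(v, "{")) {
    # list form, e.g. SET Citation = {"PubMed", "12345"}
    inner <- sub("^\\{", "", sub("\\}$", "", v))
    parts <- strsplit(inner, ",")[[1]]
    parts <- vapply(parts, function(p) {
      p <- trimws(p)
      if (startsWith(p, '"')) cur_string(new_cursor(p)) else p
    }, character(1))
    # citation lists carry (type, id [, ...]); the identifier is what we keep
    if (length(parts) >= 2) parts[2] else parts[1]
  } else {
    v
  }
}

#' Parse a BEL Script document
#'
#' Reads document metadata (`SET DOCUMENT ...`), namespace declarations
#' (`DEFINE NAMESPACE ...`), `SET`/`UNSET` annotation blocks and statement
#' lines into a knowledge graph. Syntax errors are collected as structured
#' records (line, column, message) in `kg$errors`; statements referencing
#' undeclared namespaces generate warning records in `kg$warnings`. Lines
#' are never silently dropped.
#'
#' @param text a single string, character vector of lines, or a file path
#'   (existing file)
#' @return a [bel_kg()] with `errors` and `warnings` data frames attached
#' @export
parse_bel_script <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE, encoding = "UTF-8")
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  kg <- bel_kg()
  declared <- character(0)
  current <- list()
  warned_ns <- character(0)

  add_error <- function(lineno, column, message) {
    kg$errors <<- rbind(kg$errors, data.frame(
      line = as.integer(lineno), column = as.integer(column),
      message = message, stringsAsFactors = FALSE
    ))
  }
  add_warning <- function(lineno, message) {
    kg$warnings <<- rbind(kg$warnings, data.frame(
      line = as.integer(lineno), message = message, stringsAsFactors = FALSE
    ))
  }

  for (lineno in seq_along(lines)) {
    line <- trimws(lines[[lineno]])
    if (!nzchar(line) || startsWith(line, "#")) next

    if (grepl("^SET\\s+DOCUMENT\\s+", line)) {
      m <- regmatches(line, regexec("^SET\\s+DOCUMENT\\s+([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 3) {
        key <- tolower(m[2])
        val <- unquote_value(m[3])
        if (key %in% c("name", "version")) kg$metadata[[key]] <- val
        else kg$metadata[[key]] <- val
      } else add_error(lineno, 1, "malformed SET DOCUMENT line")
      next
    }
    if (grepl("^DEFINE\\s+NAMESPACE\\s+", line)) {
      m <- regmatches(line, regexec(
        "^DEFINE\\s+NAMESPACE\\s+(\\S+)\\s+AS\\s+(URL|PATTERN)\\s+(.*)$", line))[[1]]
      if (length(m) == 4) {
        kg$metadata$namespaces[m[2]] <- unquote_value(m[4])
        declared <- c(declared, m[2])
      } else add_error(lineno, 1, "malformed DEFINE NAMESPACE line")
      next
    }
    if (grepl("^DEFINE\\s+ANNOTATION\\s+", line)) next  # accepted, not modelled
    if (grepl("^UNSET\\s+ALL$", line)) { current <- list(); next }
    if (grepl("^UNSET\\s+", line)) {
      key <- sub("^UNSET\\s+", "", line)
      current[[key]] <- NULL
      next
    }
    if (grepl("^SET\\s+", line)) {
      m <- regmatches(line, regexec("^SET\\s+([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 3) current[[m[2]]] <- unquote_value(m[3])
      else add_error(lineno, 1, "malformed SET line")
      next
    }

    # statement line
    res <- tryCatch(parse_bel_statement(line), bel_parse_error = function(e) e)
    if (inherits(res, "bel_parse_error")) {
      add_error(lineno, res$column %||% 1L, conditionMessage(res))
      next
    }
    for (ent in list(res$subject, res$object)) {
      ns <- ent$namespace
      if (ent$grounded && length(declared) && !ns %in% declared && !ns %in% warned_ns) {
        add_warning(lineno, sprintf("namespace '%s' used but not declared", ns))
        warned_ns <- c(warned_ns, ns)
      }
    }
    evidence <- current[["Evidence"]] %||% current[["SupportingText"]] %||% ""
    citation <- current[["Citation"]] %||% ""
    ann <- current[setdiff(names(current), c("Evidence", "SupportingText", "Citation"))]
    kg <- kg_add_edge(
      kg, res$subject, res$object, res$relation,
      evidence = evidence, citation = citation,
      annotations = unlist(ann) %||% character(0),
      subject_activity = res$subject_activity,
      object_activity = res$object_activity
    )
  }
  kg
}

# ---- writer ----------------------------------------------------------------

#' Write a knowledge graph as a BEL Script document
#'
#' Emits document metadata, namespace declarations (sorted by prefix), then
#' statements grouped under `SET Citation` / `SET Evidence` blocks with any
#' further annotations set per statement and unset afterwards. Ordering is
#' deterministic: statements are sorted by citation, then statement text,
#' then evidence, so `write(parse(write(x)))` is byte-stable.
#'
#' @param kg a [bel_kg()]
#' @param path optional file path; when given, the document is written there
#' @return the document as a character vector of lines (invisibly when
#'   `path` is given)
#' @export
write_bel_script <- function(kg, path = NULL) {
  stopifnot(inherits(kg, "bel_kg"))
  out <- c(
    sprintf('SET DOCUMENT Name = "%s"', bel_escape(kg$metadata$name %||% "untitled")),
    sprintf('SET DOCUMENT Version = "%s"', bel_escape(kg$metadata$version %||% "0.0.0"))
  )
  ns <- kg$metadata$namespaces
  for (prefix in sort(names(ns))) {
    out <- c(out, sprintf('DEFINE NAMESPACE %s AS URL "%s"', prefix, bel_escape(ns[[prefix]])))
  }
  out <- c(out, "")

  if (nrow(kg$edges)) {
    stmts <- vapply(seq_len(nrow(kg$edges)), kg_statement_text, character(1), kg = kg)
    ord <- order(kg$edges$citation, stmts, kg$edges$evidence, method = "radix")
    for (i in ord) {
      e <- kg$edges[i, ]
      out <- c(out, sprintf('SET Citation = "%s"', bel_escape(e$citation)))
      if (nzchar(e$evidence)) {
        out <- c(out, sprintf('SET Evidence = "%s"', bel_escape(e$evidence)))
      }
      ann <- e$annotations_list[[1]]
      ann_names <- sort(names(ann))
      for (nm in ann_names) {
        out <- c(out, sprintf('SET %s = "%s"', nm, bel_escape(ann[[nm]])))
      }
      out <- c(out, stmts[i])
      for (nm in rev(ann_names)) out <- c(out, sprintf("UNSET %s", nm))
      if (nzchar(e$evidence)) out <- c(out, "UNSET Evidence")
      out <- c(out, "UNSET Citation", "")
    }
  }
  if (!is.null(path)) {
    writeLines(out, path, useBytes = FALSE)
    return(invisible(out))
  }
  out
}
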