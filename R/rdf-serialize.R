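# RDF serialization: N-Triples (full) and a Turtle subset covering the
# constructs this package emits and the common constructs found in
# hand-written data files: @prefix/@base (and SPARQL-style PREFIX/BASE),
# prefixed names, 'a', ';' and ',' lists, bracketed anonymous nodes,
# string literals with language tags or datatypes, numbers and booleans.
# Not supported: triple-quoted strings and RDF collections.

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  # handle \\ last so escaped backslashes don't re-trigger
  vapply(x, function(s) {
    out <- character()
    i <- 1L
    chars <- strsplit(s, "")[[1]]
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        rep <- switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t", "\"" = "\"", "\\" = "\\",
          "u" = NA_character_, "U" = NA_character_, nxt
        )
        if (!is.na(rep)) {
          out <- c(out, rep)
          i <- i + 2L
          next
        }
        # \uXXXX / \UXXXXXXXX
        width <- if (nxt == "u") 4L else 8L
        hex <- paste(chars[(i + 2L):(i + 1L + width)], collapse = "")
        out <- c(out, intToUtf8(strtoi(hex, 16L)))
        i <- i + 2L + width
        next
      }
      out <- c(out, ch)
      i <- i + 1L
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

format_term_nt <- function(value, kind, lang, datatype) {
  ifelse(kind == "blank", value,
    ifelse(kind == "iri", paste0("<", value, ">"),
      paste0(
        "\"", escape_literal(value), "\"",
        ifelse(!is.na(lang), paste0("@", lang),
          ifelse(!is.na(datatype), paste0("^^<", datatype, ">"), "")
        )
      )
    )
  )
}

#' Serialize a graph to N-Triples
#'
#' Triples are emitted in a stable sorted order so identical graphs always
#' produce byte-identical output.
#'
#' @param graph An `rdf_graph`.
#' @param path Optional file path; if `NULL` the serialization is returned
#'   as a single string.
#' @return The N-Triples text (invisibly, when `path` is given).
#' @export
write_ntriples <- function(graph, path = NULL) {
  g <- sort_graph(graph)
  lines <- paste(
    ifelse(startsWith(g$subject, "_:"), g$subject, paste0("<", g$subject, ">")),
    paste0("<", g$predicate, ">"),
    format_term_nt(g$object, g$object_kind, g$lang, g$datatype),
    "."
  )
  txt <- paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Parse N-Triples text
#'
#' @param text N-Triples content as a single string or character vector of
#'   lines.
#' @return An `rdf_graph`.
#' @export
parse_ntriples <- function(text) {
  lines <- unlist(str_split(paste(text, collapse = "\n"), "\n"))
  lines <- str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_graph())
  pat <- paste0(
    "^(<[^>]*>|_:\\S+)\\s+",
    "<([^>]*)>\\s+",
    "(<[^>]*>|_:\\S+|\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z0-9-]+|\\^\\^<[^>]*>)?)",
    "\\s*\\.\\s*$"
  )
  m <- str_match(lines, pat)
  bad <- which(is.na(m[, 1]))
  if (length(bad)) {
    abort(glue("N-Triples parse error at line {bad[1]}: {lines[bad[1]]}"),
      class = "faircheckr_parse_error"
    )
  }
  subj <- ifelse(startsWith(m[, 2], "<"), str_sub(m[, 2], 2, -2), m[, 2])
  obj_raw <- m[, 4]
  parse_obj <- function(o) {
    if (startsWith(o, "<")) {
      c(str_sub(o, 2, -2), "iri", NA, NA)
    } else if (startsWith(o, "_:")) {
      c(o, "blank", NA, NA)
    } else {
      mm <- str_match(o, "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:@([A-Za-z0-9-]+)|\\^\\^<([^>]*)>)?$")
      c(unescape_literal(mm[2]), "literal", mm[3], mm[4])
    }
  }
  parts <- t(vapply(obj_raw, parse_obj, character(4), USE.NAMES = FALSE))
  as_rdf_graph(tibble(
    subject = subj, predicate = m[, 3],
    object = parts[, 1], object_kind = parts[, 2],
    lang = parts[, 3], datatype = parts[, 4]
  ))
}

# ---- Turtle ----------------------------------------------------------------

ttl_token_pattern <- paste0(
  "(?:",
  "<[^<>\"{}|^`\\\\\\s]*>",                                  # IRIREF
  "|\"(?:[^\"\\\\\\n]|\\\\.)*\"",                            # STRING
  "|@prefix|@base|@[A-Za-z]+(?:-[A-Za-z0-9]+)*",             # directives / langtag
  "|\\^\\^",
  "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_%-]|\\.(?=[A-Za-z0-9_%-]))*", # PNAME
  "|_:[A-Za-z0-9][A-Za-z0-9_-]*",                            # blank node label
  "|[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",          # number
  "|[A-Za-z][A-Za-z0-9_]*",                                  # bare word (a, true, PREFIX)
  "|#[^\\n]*",                                               # comment
  "|[;,.\\[\\]()]",
  ")"
)

ttl_tokenize <- function(text) {
  m <- gregexpr(ttl_token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(text, list(m))[[1]]
  # verify nothing but whitespace was skipped between tokens
  covered <- sum(attr(m, "match.length"))
  residue <- gsub(ttl_token_pattern, "", text, perl = TRUE)
  if (grepl("\\S", residue)) {
    abort(glue("Turtle parse error: unexpected input near '{substr(str_trim(residue), 1, 40)}'"),
      class = "faircheckr_parse_error"
    )
  }
  toks[!startsWith(toks, "#")]
}

#' Parse Turtle text
#'
#' Supports the Turtle subset described in the package vignette:
#' prefixes, base, prefixed names, `a`, predicate/object lists, anonymous
#' bracketed nodes, typed and language-tagged literals, numbers, booleans.
#'
#' @param text Turtle content as a single string.
#' @param base Optional base IRI for resolving relative references.
#' @return An `rdf_graph`.
#' @export
parse_turtle <- function(text, base = NA_character_) {
  text <- paste(text, collapse = "\n")
  toks <- ttl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  st$prefixes <- character()
  st$base <- base
  st$rows <- vector("list", 0)
  st$bnode <- blank_factory("t")

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NA_character_
  advance <- function() {
    t <- peek()
    st$i <- st$i + 1L
    t
  }
  expect <- function(tok) {
    t <- advance()
    if (is.na(t) || t != tok) {
      abort(glue("Turtle parse error: expected '{tok}' near token {st$i} ('{t %||% 'EOF'}')"),
        class = "faircheckr_parse_error"
      )
    }
  }
  emit <- function(s, p, o, kind, lang = NA_character_, dt = NA_character_) {
    st$rows[[length(st$rows) + 1L]] <- list(
      subject = s, predicate = p, object = o,
      object_kind = kind, lang = lang, datatype = dt
    )
  }
  expand_pname <- function(tok) {
    m <- str_match(tok, "^([^:]*):(.*)$")
    pfx <- m[2]
    if (!pfx %in% names(st$prefixes)) {
      abort(glue("Turtle parse error: undeclared prefix '{pfx}:'"),
        class = "faircheckr_parse_error"
      )
    }
    paste0(st$prefixes[[pfx]], m[3])
  }
  resolve <- function(iri) {
    if (!is.na(st$base) && !is_absolute_iri(iri)) resolve_one(iri, st$base) else iri
  }
  term <- function(tok) {
    # returns list(value, kind, lang, dt); consumes extra tokens for literals
    if (startsWith(tok, "<")) {
      return(list(resolve(str_sub(tok, 2, -2)), "iri", NA_character_, NA_character_))
    }
    if (startsWith(tok, "_:")) {
      return(list(tok, "blank", NA_character_, NA_character_))
    }
    if (startsWith(tok, "\"")) {
      val <- unescape_literal(str_sub(tok, 2, -2))
      nxt <- peek()
      if (!is.na(nxt) && startsWith(nxt, "@") && !nxt %in% c("@prefix", "@base")) {
        advance()
        return(list(val, "literal", str_sub(nxt, 2), NA_character_))
      }
      if (!is.na(nxt) && nxt == "^^") {
        advance()
        dt <- term(advance())
        return(list(val, "literal", NA_character_, dt[[1]]))
      }
      return(list(val, "literal", NA_character_, NA_character_))
    }
    if (tok %in% c("true", "false")) {
      return(list(tok, "literal", NA_character_, expand_curie("xsd:boolean")))
    }
    if (str_detect(tok, "^[+-]?[0-9]")) {
      dt <- if (str_detect(tok, "[.eE]")) "xsd:decimal" else "xsd:integer"
      return(list(tok, "literal", NA_character_, expand_curie(dt)))
    }
    if (str_detect(tok, ":")) {
      return(list(expand_pname(tok), "iri", NA_character_, NA_character_))
    }
    abort(glue("Turtle parse error: unexpected token '{tok}'"),
      class = "faircheckr_parse_error"
    )
  }
  verb <- function() {
    tok <- advance()
    if (identical(tok, "a")) return(RDF_TYPE)
    t <- term(tok)
    if (t[[2]] != "iri") {
      abort("Turtle parse error: predicate must be an IRI",
        class = "faircheckr_parse_error"
      )
    }
    t[[1]]
  }
  object_term <- function() {
    tok <- advance()
    if (identical(tok, "[")) {
      b <- st$bnode()
      if (!identical(peek(), "]")) predicate_object_list(b)
      expect("]")
      return(list(b, "blank", NA_character_, NA_character_))
    }
    term(tok)
  }
  predicate_object_list <- function(subj) {
    repeat {
      p <- verb()
      repeat {
        o <- object_term()
        emit(subj, p, o[[1]], o[[2]], o[[3]], o[[4]])
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (identical(peek(), ".") || identical(peek(), "]")) break
      } else {
        break
      }
    }
  }

  while (!is.na(peek())) {
    tok <- peek()
    if (tok == "@prefix" || tolower(tok) == "prefix") {
      advance()
      pn <- advance()
      pfx <- str_match(pn, "^([^:]*):$")[2]
      iri_tok <- advance()
      st$prefixes[[pfx %||% ""]] <- str_sub(iri_tok, 2, -2)
      if (identical(peek(), ".")) advance()
    } else if (tok == "@base" || tolower(tok) == "base") {
      advance()
      st$base <- str_sub(advance(), 2, -2)
      if (identical(peek(), ".")) advance()
    } else {
      subj_tok <- advance()
      if (identical(subj_tok, "[")) {
        s <- st$bnode()
        if (!identical(peek(), "]")) predicate_object_list(s)
        expect("]")
      } else {
        t <- term(subj_tok)
        if (t[[2]] == "literal") {
          abort("Turtle parse error: literal subject", class = "faircheckr_parse_error")
        }
        s <- t[[1]]
      }
      predicate_object_list(s)
      expect(".")
    }
  }
  if (length(st$rows) == 0) return(empty_graph())
  as_rdf_graph(bind_rows(lapply(st$rows, as_tibble)))
}

pname_safe <- function(local) {
  str_detect(local, "^[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?$")
}

format_iri_ttl <- function(iri, prefixes_used) {
  ns <- fair_namespaces()
  for (p in names(ns)) {
    if (startsWith(iri, ns[[p]])) {
      local <- substr(iri, nchar(ns[[p]]) + 1L, nchar(iri))
      if (pname_safe(local) || local == "") {
        prefixes_used$add(p)
        return(paste0(p, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

#' Serialize a graph to Turtle
#'
#' Output is deterministic (sorted subjects and predicates, known prefixes
#' compacted) so a fixed graph always serializes to identical bytes.
#'
#' @param graph An `rdf_graph`.
#' @param path Optional output file path.
#' @return Turtle text (invisibly when `path` is given).
#' @export
write_turtle <- function(graph, path = NULL) {
  g <- sort_graph(graph)
  used <- new.env(parent = emptyenv())
  used$set <- character()
  used$add <- function(p) used$set <- union(used$set, p)

  fmt_term <- function(value, kind, lang, dt) {
    if (kind == "blank") return(value)
    if (kind == "iri") return(format_iri_ttl(value, used))
    out <- paste0("\"", escape_literal(value), "\"")
    if (!is.na(lang)) return(paste0(out, "@", lang))
    if (!is.na(dt)) return(paste0(out, "^^", format_iri_ttl(dt, used)))
    out
  }

  body <- character()
  if (nrow(g)) {
    for (s in unique(g$subject)) {
      rows <- g[g$subject == s, ]
      subj <- if (startsWith(s, "_:")) s else format_iri_ttl(s, used)
      stmts <- vapply(seq_len(nrow(rows)), function(i) {
        p <- if (rows$predicate[i] == RDF_TYPE) "a" else format_iri_ttl(rows$predicate[i], used)
        o <- fmt_term(rows$object[i], rows$object_kind[i], rows$lang[i], rows$datatype[i])
        paste0("    ", p, " ", o)
      }, character(1))
      body <- c(body, paste0(subj, "\n", paste(stmts, collapse = " ;\n"), " ."))
    }
  }
  ns <- fair_namespaces()
  header <- vapply(sort(used$set), function(p) {
    paste0("@prefix ", p, ": <", ns[[p]], "> .")
  }, character(1))
  txt <- paste0(
    paste(c(header, "", body), collapse = "\n"),
    if (length(body)) "\n" else ""
  )
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Read an RDF file in a declared serialization
#'
#' @param path File path.
#' @param serialization One of `"turtle"`, `"ntriples"`, `"json-ld"`,
#'   `"rdfxml"`.
#' @param base Optional base IRI.
#' @return An `rdf_graph`.
#' @export
read_rdf <- function(path, serialization = c("turtle", "ntriples", "json-ld", "rdfxml"),
                     base = NA_character_) {
  serialization <- match.arg(serialization)
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  switch(serialization,
    turtle = parse_turtle(txt, base = base),
    ntriples = parse_ntriples(txt),
    `json-ld` = parse_jsonld(txt, base = base),
    rdfxml = parse_rdfxml(txt, base = base)
  )
}
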