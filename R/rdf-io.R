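# RDF input/output: N-Triples reader/writer and a Turtle-subset reader.
#
# Supported Turtle subset: @prefix/@base and SPARQL-style PREFIX/BASE
# directives, IRIs, prefixed names, 'a', blank node labels (_:x),
# predicate-object lists (';'), object lists (','), short and long quoted
# literals with language tags or datatypes, numeric and boolean literals.
# Not supported (out of scope): collections '( )' and anonymous blank node
# property lists '[ ]'.

RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

.nt_unescape <- function(x) {
  if (!grepl("\\\\", x)) return(x)
  out <- character(0)
  i <- 1L; n <- nchar(x)
  while (i <= n) {
    ch <- substr(x, i, i)
    if (ch == "\\" && i < n) {
      nx <- substr(x, i + 1L, i + 1L)
      if (nx == "u") {
        code <- strtoi(substr(x, i + 2L, i + 5L), 16L)
        out <- c(out, intToUtf8(code)); i <- i + 6L
      } else if (nx == "U") {
        code <- strtoi(substr(x, i + 2L, i + 9L), 16L)
        out <- c(out, intToUtf8(code)); i <- i + 10L
      } else {
        out <- c(out, switch(nx, n = "\n", t = "\t", r = "\r", b = "\b",
                             f = "\f", nx))
        i <- i + 2L
      }
    } else {
      out <- c(out, ch); i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

.nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.empty_triples <- function() {
  data.frame(subject = character(), subject_type = character(),
             predicate = character(),
             object = character(), object_type = character(),
             object_lang = character(), object_datatype = character(),
             stringsAsFactors = FALSE)
}

.triple_row <- function(s, st, p, o, ot, lang = NA_character_,
                        dt = NA_character_) {
  list(subject = s, subject_type = st, predicate = p, object = o,
       object_type = ot, object_lang = lang, object_datatype = dt)
}

# ---- N-Triples ----

.parse_ntriples <- function(lines) {
  iri <- "<[^>]*>"
  bnode <- "_:[A-Za-z0-9][A-Za-z0-9_.-]*"
  lit <- paste0("\"(?:[^\"\\\\]|\\\\.)*\"",
                "(?:@[A-Za-z]+(?:-[A-Za-z0-9]+)*|\\^\\^<[^>]*>)?")
  re <- paste0("^[ \t]*((?:", iri, ")|(?:", bnode, "))[ \t]+(", iri,
               ")[ \t]+((?:", iri, ")|(?:", bnode, ")|(?:", lit,
               "))[ \t]*\\.[ \t]*$")
  lit_re <- paste0("^\"((?:[^\"\\\\]|\\\\.)*)\"",
                   "(?:@([A-Za-z]+(?:-[A-Za-z0-9]+)*)|\\^\\^<([^>]*)>)?$")
  strip_iri <- function(x) .nt_unescape(substr(x, 2L, nchar(x) - 1L))
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (grepl("^[ \t]*$", ln) || grepl("^[ \t]*#", ln)) next
    m <- regmatches(ln, regexec(re, ln, perl = TRUE))[[1]]
    if (length(m) == 0L)
      stop(sprintf("N-Triples parse error at line %d: %s", k, trimws(ln)),
           call. = FALSE)
    s_raw <- m[2]; p <- strip_iri(m[3]); o_raw <- m[4]
    s <- if (startsWith(s_raw, "<")) strip_iri(s_raw) else s_raw
    st <- if (startsWith(s_raw, "<")) "iri" else "blank"
    if (startsWith(o_raw, "<")) {
      rows[[k]] <- .triple_row(s, st, p, strip_iri(o_raw), "iri")
    } else if (startsWith(o_raw, "_:")) {
      rows[[k]] <- .triple_row(s, st, p, o_raw, "blank")
    } else {
      lm <- regmatches(o_raw, regexec(lit_re, o_raw, perl = TRUE))[[1]]
      rows[[k]] <- .triple_row(
        s, st, p, .nt_unescape(lm[2]), "literal",
        if (nzchar(lm[3])) lm[3] else NA_character_,
        if (nzchar(lm[4])) lm[4] else NA_character_)
    }
  }
  rows
}

# ---- Turtle ----

.ttl_tokenize <- function(text) {
  specs <- list(
    c("ws",      "[ \t\r\n]+|#[^\n]*"),
    c("prefix",  "@prefix(?![A-Za-z])|PREFIX(?![A-Za-z])|prefix(?![A-Za-z])"),
    c("base",    "@base(?![A-Za-z])|BASE(?![A-Za-z])|base(?![A-Za-z])"),
    c("iriref",  "<[^>]*>"),
    c("string",  paste0("\"\"\"(?:[^\"\\\\]|\\\\.|\"(?!\"\"))*\"\"\"",
                        "|'''(?:[^'\\\\]|\\\\.|'(?!''))*'''",
                        "|\"(?:[^\"\\\\\n]|\\\\.)*\"",
                        "|'(?:[^'\\\\\n]|\\\\.)*'")),
    c("caret",   "\\^\\^"),
    c("langtag", "@[A-Za-z]+(?:-[A-Za-z0-9]+)*"),
    c("bnode",   "_:[A-Za-z0-9_][A-Za-z0-9_.-]*(?<!\\.)"),
    c("boolean", "true(?![\\w:.-])|false(?![\\w:.-])"),
    c("kw_a",    "a(?![\\w:.-])"),
    c("number",  "[+-]?(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?"),
    c("pname",   "(?:[A-Za-z_][\\w.-]*)?:(?:[\\w%-]|\\.(?=[\\w%.-]))*"),
    c("punct",   "[.;,]")
  )
  pos <- 1L; n <- nchar(text)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  if (length(nl) == 1L && nl[1] == -1L) nl <- integer(0)
  line_of <- function(p) findInterval(p - 1L, nl) + 1L
  types <- character(0); values <- character(0); lines_ <- integer(0)
  while (pos <= n) {
    hit <- FALSE
    for (sp in specs) {
      m <- regexpr(paste0("^(?:", sp[2], ")"),
                   substr(text, pos, min(n, pos + 100000L)), perl = TRUE)
      if (m != -1L) {
        len <- attr(m, "match.length")
        if (sp[1] != "ws") {
          types <- c(types, sp[1])
          values <- c(values, substr(text, pos, pos + len - 1L))
          lines_ <- c(lines_, line_of(pos))
        }
        pos <- pos + len
        hit <- TRUE
        break
      }
    }
    if (!hit)
      stop(sprintf("Turtle tokenizer error at line %d near '%s'",
                   line_of(pos), substr(text, pos, pos + 20L)),
           call. = FALSE)
  }
  data.frame(type = types, value = values, line = lines_,
             stringsAsFactors = FALSE)
}

.ttl_strip_string <- function(v) {
  if (startsWith(v, "\"\"\"") || startsWith(v, "'''"))
    .nt_unescape(substr(v, 4L, nchar(v) - 3L))
  else
    .nt_unescape(substr(v, 2L, nchar(v) - 1L))
}

.parse_turtle <- function(text) {
  tok <- .ttl_tokenize(text)
  prefixes <- list()
  base <- NULL
  i <- 1L
  nt <- nrow(tok)
  rows <- list()
  perr <- function(msg, at = i) {
    line <- if (at <= nt) tok$line[at] else if (nt) tok$line[nt] else 1L
    stop(sprintf("Turtle parse error at line %d: %s", line, msg),
         call. = FALSE)
  }
  peek <- function() if (i <= nt) tok$type[i] else "eof"
  resolve_iri <- function(v) {
    v <- .nt_unescape(substr(v, 2L, nchar(v) - 1L))
    if (!is.null(base) && !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", v))
      v <- paste0(base, v)
    v
  }
  resolve_pname <- function(v, at) {
    cpos <- regexpr(":", v, fixed = TRUE)
    pfx <- substr(v, 1L, cpos - 1L)
    local <- substr(v, cpos + 1L, nchar(v))
    if (is.null(prefixes[[paste0(pfx, ":")]]))
      perr(sprintf("undeclared prefix '%s:'", pfx), at)
    paste0(prefixes[[paste0(pfx, ":")]], local)
  }
  # returns list(value, type, lang, datatype); advances i
  term <- function(role) {
    if (i > nt) perr("unexpected end of input")
    ty <- tok$type[i]; v <- tok$value[i]; at <- i
    if (ty == "iriref") {
      i <<- i + 1L
      return(list(v = resolve_iri(v), t = "iri"))
    }
    if (ty == "pname") {
      i <<- i + 1L
      return(list(v = resolve_pname(v, at), t = "iri"))
    }
    if (ty == "kw_a" && role == "predicate") {
      i <<- i + 1L
      return(list(v = RDF_TYPE_IRI, t = "iri"))
    }
    if (ty == "bnode" && role != "predicate") {
      i <<- i + 1L
      return(list(v = v, t = "blank"))
    }
    if (role == "object") {
      if (ty == "string") {
        lex <- .ttl_strip_string(v)
        i <<- i + 1L
        lang <- NA_character_; dt <- NA_character_
        if (peek() == "langtag") {
          lang <- substr(tok$value[i], 2L, nchar(tok$value[i]))
          i <<- i + 1L
        } else if (peek() == "caret") {
          i <<- i + 1L
          dtt <- term("datatype")
          dt <- dtt$v
        }
        return(list(v = lex, t = "literal", lang = lang, dt = dt))
      }
      if (ty == "number") {
        i <<- i + 1L
        return(list(v = v, t = "literal", lang = NA_character_,
                    dt = "http://www.w3.org/2001/XMLSchema#decimal"))
      }
      if (ty == "boolean") {
        i <<- i + 1L
        return(list(v = v, t = "literal", lang = NA_character_,
                    dt = "http://www.w3.org/2001/XMLSchema#boolean"))
      }
    }
    if (role == "datatype") perr("expected datatype IRI after '^^'", at)
    perr(sprintf("unexpected token '%s' as %s", v, role), at)
  }
  expect_punct <- function(p) {
    if (i > nt || tok$type[i] != "punct" || tok$value[i] != p)
      perr(sprintf("expected '%s'", p))
    i <<- i + 1L
  }
  while (i <= nt) {
    ty <- tok$type[i]
    if (ty == "prefix") {
      sparql <- !startsWith(tok$value[i], "@")
      i <- i + 1L
      if (peek() != "pname") perr("expected prefix name in @prefix")
      pn <- tok$value[i]
      if (!grepl(":$", pn)) perr("prefix declaration must end in ':'")
      i <- i + 1L
      if (peek() != "iriref") perr("expected IRI in @prefix")
      prefixes[[pn]] <- resolve_iri(tok$value[i])
      i <- i + 1L
      if (!sparql) expect_punct(".")
      next
    }
    if (ty == "base") {
      sparql <- !startsWith(tok$value[i], "@")
      i <- i + 1L
      if (peek() != "iriref") perr("expected IRI in @base")
      base <- resolve_iri(tok$value[i])
      i <- i + 1L
      if (!sparql) expect_punct(".")
      next
    }
    subj <- term("subject")
    repeat {
      pred <- term("predicate")
      repeat {
        obj <- term("object")
        rows[[length(rows) + 1L]] <- .triple_row(
          subj$v, subj$t, pred$v, obj$v, obj$t,
          if (is.null(obj$lang)) NA_character_ else obj$lang,
          if (is.null(obj$dt)) NA_character_ else obj$dt)
        if (i <= nt && tok$type[i] == "punct" && tok$value[i] == ",") {
          i <- i + 1L
        } else break
      }
      if (i <= nt && tok$type[i] == "punct" && tok$value[i] == ";") {
        i <- i + 1L
        # trailing ';' before '.' is legal
        if (i <= nt && tok$type[i] == "punct" && tok$value[i] == ".") break
      } else break
    }
    expect_punct(".")
  }
  rows
}

#' Read RDF triples
#'
#' Reads a file of RDF triples in N-Triples or Turtle serialization into a
#' triple table. Literal lexical forms are preserved (escape sequences
#' decoded); language tags and datatype IRIs are kept in their own columns.
#' The Turtle reader covers the common subset documented in the package
#' vignette (no collections or anonymous blank-node property lists).
#'
#' @param path file path.
#' @param format `"ntriples"` or `"turtle"`.
#' @return a data.frame with columns `subject`, `subject_type`
#'   (`"iri"`/`"blank"`), `predicate`, `object`, `object_type`
#'   (`"iri"`/`"blank"`/`"literal"`), `object_lang`, `object_datatype`,
#'   one row per triple in file order.
#' @examples
#' f <- tempfile(fileext = ".nt")
#' writeLines('<urn:a> <urn:p> "hello" .', f)
#' readTriples(f, "ntriples")
#' @export
readTriples <- function(path, format = c("ntriples", "turtle")) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("ntriples", "turtle"))
    stop("unknown RDF format: ", paste(format, collapse = ","),
         " (supported: ntriples, turtle)")
  if (!file.exists(path)) stop("file not found: ", path)
  rows <- if (format == "ntriples") {
    .parse_ntriples(readLines(path, encoding = "UTF-8", warn = FALSE))
  } else {
    .parse_turtle(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                        collapse = "\n"))
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(.empty_triples())
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write a triple table as N-Triples
#'
#' Inverse of [readTriples()] for the N-Triples serialization. Literals
#' with a language tag or datatype are written with their annotation.
#'
#' @param triples triple table as returned by [readTriples()] or
#'   [makePlantedKG()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNTriples <- function(triples, path) {
  fmt_node <- function(v, t) {
    ifelse(t == "blank", v, paste0("<", .nt_escape(v), ">"))
  }
  s <- fmt_node(triples$subject, triples$subject_type)
  p <- paste0("<", .nt_escape(triples$predicate), ">")
  o <- character(nrow(triples))
  for (k in seq_len(nrow(triples))) {
    if (triples$object_type[k] == "literal") {
      ann <- ""
      if (!is.na(triples$object_lang[k]))
        ann <- paste0("@", triples$object_lang[k])
      else if (!is.na(triples$object_datatype[k]))
        ann <- paste0("^^<", triples$object_datatype[k], ">")
      o[k] <- paste0("\"", .nt_escape(triples$object[k]), "\"", ann)
    } else {
      o[k] <- fmt_node(triples$object[k], triples$object_type[k])
    }
  }
  writeLines(paste(s, p, o, "."), path, useBytes = TRUE)
  invisible(path)
}

#' Read a predicate exclusion list
#'
#' Plain-text file with one predicate IRI per line (blank lines and lines
#' starting with `#` ignored). Used to drop label-leaking predicates before
#' graph conversion.
#'
#' @param path file path.
#' @return character vector of predicate IRIs.
#' @export
readPredicateExclusions <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
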