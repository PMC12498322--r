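# KEGG module DEFINITION parsing and module-coverage feature vectors.
#
# A DEFINITION string describes a functional module as an ordered list of
# steps (space-separated at the top level). Within an expression, commas
# denote alternatives (OR), spaces inside parentheses denote required
# components (AND), '+' joins members of a protein complex (AND), and a
# '-' prefix marks a component as optional (it never counts against
# completeness). Module completeness of a KO set is the fraction of steps
# whose boolean expression evaluates true with "leaf true iff the KO is
# present", optional leaves always true.

KO_PATTERN <- "^K[0-9]{5}$"

# ---- KO profiles -----------------------------------------------------------

#' Construct a KO annotation profile
#'
#' A `ko_profile` is the multiset of KEGG Orthology (KO) annotations of one
#' genome or bin: a named count vector plus its total. Zero counts are
#' dropped; the profile is the raw material both for module-coverage
#' features and for the incompleteness subsampler.
#'
#' @param genome_id genome or bin identifier.
#' @param counts named integer vector, names are K-numbers, values are
#'   annotation counts (>= 1). An empty vector gives an empty profile.
#' @return an object of class `ko_profile` with fields `genome_id`,
#'   `counts` and `total`.
#' @examples
#' ko_profile("g1", c(K00001 = 2, K00002 = 1))
#' @export
ko_profile <- function(genome_id, counts = integer(0)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  counts <- counts[counts > 0]
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("counts must be a named vector of K-numbers", call. = FALSE)
    }
    bad <- names(counts)[!grepl(KO_PATTERN, names(counts))]
    if (length(bad)) {
      stop("invalid KO identifier(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    counts <- counts[order(names(counts))]
  }
  storage.mode(counts) <- "integer"
  structure(list(genome_id = genome_id, counts = counts,
                 total = sum(counts)),
            class = "ko_profile")
}

#' @export
print.ko_profile <- function(x, ...) {
  cat(sprintf("<ko_profile> %s: %d annotations over %d KOs\n",
              x$genome_id, x$total, length(x$counts)))
  invisible(x)
}

# KOs present in a profile (presence is binary: count > 0).
profile_kos <- function(profile) names(profile$counts)

# ---- DEFINITION tokenizer and parser ---------------------------------------

tokenize_definition <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("(", ")", ",", "+", "-", " ")) {
      type <- switch(ch, "(" = "lparen", ")" = "rparen", "," = "comma",
                     "+" = "plus", "-" = "minus", " " = "space")
      tokens[[length(tokens) + 1L]] <- list(type = type, pos = i)
      i <- i + 1L
    } else if (grepl("[A-Za-z0-9_.]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_.]", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      if (!grepl(KO_PATTERN, word)) {
        stop(sprintf("definition parse error at position %d: '%s' is not a K-number",
                     i, word), call. = FALSE)
      }
      tokens[[length(tokens) + 1L]] <- list(type = "ko", value = word, pos = i)
      i <- j
    } else {
      stop(sprintf("definition parse error at position %d: unexpected character '%s'",
                   i, ch), call. = FALSE)
    }
  }
  tokens
}

# Recursive-descent parser over a token stream held in a mutable cursor
# environment. Precedence (loosest to tightest): comma (OR), space (AND),
# +/- (complex / optional member).
new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}
cur_peek <- function(cur) {
  if (cur$i > length(cur$tokens)) NULL else cur$tokens[[cur$i]]
}
cur_next <- function(cur) {
  tok <- cur_peek(cur)
  cur$i <- cur$i + 1L
  tok
}

leaf_node <- function(ko, optional = FALSE) {
  list(kind = "leaf", ko = ko, optional = optional)
}
op_node <- function(op, children, joiner = NULL) {
  if (length(children) == 1L) return(children[[1L]])
  list(kind = "op", op = op, joiner = joiner, children = children)
}

parse_or <- function(cur) {
  children <- list(parse_and(cur))
  while (!is.null(tok <- cur_peek(cur)) && tok$type == "comma") {
    cur_next(cur)
    children[[length(children) + 1L]] <- parse_and(cur)
  }
  op_node("ANY", children)
}

parse_and <- function(cur) {
  children <- list(parse_complex(cur))
  while (!is.null(tok <- cur_peek(cur)) && tok$type == "space") {
    cur_next(cur)
    children[[length(children) + 1L]] <- parse_complex(cur)
  }
  op_node("ALL", children, joiner = "space")
}

parse_complex <- function(cur) {
  children <- list(parse_unary(cur))
  while (!is.null(tok <- cur_peek(cur)) && tok$type %in% c("plus", "minus")) {
    op <- cur_next(cur)$type
    child <- parse_primary(cur)
    if (op == "minus") child <- mark_optional(child)
    children[[length(children) + 1L]] <- child
  }
  op_node("ALL", children, joiner = "plus")
}

parse_unary <- function(cur) {
  tok <- cur_peek(cur)
  if (!is.null(tok) && tok$type == "minus") {
    cur_next(cur)
    return(mark_optional(parse_primary(cur)))
  }
  parse_primary(cur)
}

parse_primary <- function(cur) {
  tok <- cur_next(cur)
  if (is.null(tok)) stop("definition parse error: unexpected end of input",
                         call. = FALSE)
  if (tok$type == "ko") return(leaf_node(tok$value))
  if (tok$type == "lparen") {
    node <- parse_or(cur)
    closing <- cur_next(cur)
    if (is.null(closing) || closing$type != "rparen") {
      stop(sprintf("definition parse error at position %d: unbalanced '('",
                   tok$pos), call. = FALSE)
    }
    return(node)
  }
  stop(sprintf("definition parse error at position %d: unexpected '%s'",
               tok$pos, tok$type), call. = FALSE)
}

mark_optional <- function(node) {
  if (node$kind == "leaf") {
    node$optional <- TRUE
  } else {
    node$children <- lapply(node$children, mark_optional)
  }
  node
}

collect_leaves <- function(node) {
  if (node$kind == "leaf") {
    return(data.frame(ko = node$ko, optional = node$optional,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(node$children, collect_leaves))
}

#' Parse a KEGG module DEFINITION string
#'
#' Splits the definition into top-level space-separated steps and parses
#' each step into a boolean expression tree over K-numbers. Commas denote
#' alternatives (OR); spaces within parentheses and `+` denote required
#' components (AND); a `-` prefix marks an optional component.
#'
#' @param module_id module identifier (e.g. `"M00165"`).
#' @param definition_text the DEFINITION string.
#' @return an object of class `module_definition` with fields `module_id`,
#'   `steps` (list of expression trees), `optional_leaves` and `kos`
#'   (distinct non-optional K-numbers).
#' @examples
#' m <- parse_module_definition("M_toy", "(K00001,K00003) K00002")
#' n_steps(m)
#' @export
parse_module_definition <- function(module_id, definition_text) {
  stopifnot(is.character(module_id), length(module_id) == 1L,
            is.character(definition_text), length(definition_text) == 1L)
  definition_text <- trimws(definition_text)
  if (!nzchar(definition_text)) {
    stop("empty module definition for ", module_id, call. = FALSE)
  }
  tokens <- tokenize_definition(definition_text)

  # Split the token stream at depth-0 spaces: one segment per step.
  depth <- 0L
  seg_breaks <- integer(0)
  for (k in seq_along(tokens)) {
    t <- tokens[[k]]
    if (t$type == "lparen") depth <- depth + 1L
    if (t$type == "rparen") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("definition parse error at position %d: unbalanced ')'",
                     t$pos), call. = FALSE)
      }
    }
    if (t$type == "space" && depth == 0L) seg_breaks <- c(seg_breaks, k)
  }
  if (depth != 0L) {
    stop("definition parse error: unbalanced '(' in ", module_id,
         call. = FALSE)
  }
  bounds <- c(0L, seg_breaks, length(tokens) + 1L)
  steps <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    seg <- tokens[seq_len(length(tokens)) > bounds[s] &
                  seq_len(length(tokens)) < bounds[s + 1L]]
    if (!length(seg)) next
    cur <- new_cursor(seg)
    node <- parse_or(cur)
    left <- cur_peek(cur)
    if (!is.null(left)) {
      stop(sprintf("definition parse error at position %d: trailing '%s'",
                   left$pos, left$type), call. = FALSE)
    }
    steps[[length(steps) + 1L]] <- node
  }
  if (!length(steps)) {
    stop("module definition has no steps: ", module_id, call. = FALSE)
  }
  leaves <- do.call(rbind, lapply(steps, collect_leaves))
  structure(list(module_id = module_id,
                 steps = steps,
                 optional_leaves = sort(unique(leaves$ko[leaves$optional])),
                 kos = sort(unique(leaves$ko[!leaves$optional]))),
            class = "module_definition")
}

#' Number of steps in a module definition
#' @param definition a `module_definition`.
#' @export
n_steps <- function(definition) {
  stopifnot(inherits(definition, "module_definition"))
  length(definition$steps)
}

serialize_node <- function(node, parent = "top") {
  if (node$kind == "leaf") {
    return(paste0(if (node$optional) "-" else "", node$ko))
  }
  sep <- if (node$op == "ANY") "," else if (identical(node$joiner, "plus")) "+" else " "
  parts <- vapply(node$children, function(ch) {
    s <- serialize_node(ch, parent = node$op)
    # parenthesize when a looser operator sits under a tighter one
    needs <- ch$kind == "op" &&
      ((node$op == "ALL" && identical(node$joiner, "plus")) ||
       (node$op == "ALL" && ch$op == "ANY") ||
       (node$op == "ANY" && ch$op == "ALL" &&
        identical(ch$joiner, "space")))
    if (needs) paste0("(", s, ")") else s
  }, character(1))
  # '+'-joined optional members serialize via the leading '-' of the child
  out <- parts[1]
  if (length(parts) > 1) {
    for (p in parts[-1]) {
      if (sep == "+" && startsWith(p, "-")) out <- paste0(out, p)
      else out <- paste0(out, sep, p)
    }
  }
  out
}

#' Canonical serialization of a module definition
#' @param x a `module_definition`.
#' @param ... unused.
#' @return the DEFINITION string in canonical form; reparsing it yields an
#'   equivalent definition.
#' @export
format.module_definition <- function(x, ...) {
  paste(vapply(x$steps, function(s) {
    txt <- serialize_node(s)
    if (s$kind == "op" && s$op == "ALL" && identical(s$joiner, "space")) {
      txt <- paste0("(", txt, ")")
    }
    txt
  }, character(1)), collapse = " ")
}

#' @export
print.module_definition <- function(x, ...) {
  cat(sprintf("<module_definition> %s: %d step(s), %d KO(s)\n  %s\n",
              x$module_id, n_steps(x), length(x$kos), format(x)))
  invisible(x)
}

# ---- Completeness evaluation -----------------------------------------------

eval_node <- function(node, present) {
  if (node$kind == "leaf") {
    return(node$optional || node$ko %in% present)
  }
  vals <- vapply(node$children, eval_node, logical(1), present = present)
  if (node$op == "ANY") any(vals) else all(vals)
}

#' Module completeness of a KO set
#'
#' The fraction of the module's steps whose boolean expression is satisfied
#' by the given KO set. Optional components always count as present, so
#' they never lower (or raise) the score.
#'
#' @param definition a `module_definition`.
#' @param present_kos character vector of present K-numbers (may be empty).
#' @return a fraction in \[0, 1\].
#' @examples
#' m <- parse_module_definition("M_toy", "K00001 K00002")
#' module_completeness(m, "K00001")  # 0.5
#' @export
module_completeness <- function(definition, present_kos) {
  stopifnot(inherits(definition, "module_definition"))
  present_kos <- as.character(present_kos)
  satisfied <- vapply(definition$steps, eval_node, logical(1),
                      present = present_kos)
  sum(satisfied) / length(satisfied)
}

# ---- Coverage vectors ------------------------------------------------------

#' Module-coverage feature vector of a KO profile
#'
#' Evaluates every module in the catalog against the KOs present in the
#' profile. The result is the fixed-order feature vector consumed by the
#' completeness regressors. Presence is binary: annotation counts beyond 1
#' do not change module completeness.
#'
#' @param profile a `ko_profile`.
#' @param catalog list of `module_definition`s with unique ids.
#' @param mode `"fraction"` (per-module fractional completeness, default)
#'   or `"binary"` (1 only for fully complete modules).
#' @return an object of class `coverage_vector`: fields `genome_id`,
#'   `module_order` and `values` (named numeric in \[0, 1\]).
#' @export
coverage_vector <- function(profile, catalog, mode = c("fraction", "binary")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "ko_profile"))
  check_catalog(catalog)
  ids <- vapply(catalog, function(m) m$module_id, character(1))
  present <- profile_kos(profile)
  vals <- vapply(catalog, module_completeness, numeric(1),
                 present_kos = present)
  if (mode == "binary") vals <- as.numeric(vals >= 1)
  names(vals) <- ids
  structure(list(genome_id = profile$genome_id,
                 module_order = ids,
                 values = vals),
            class = "coverage_vector")
}

check_catalog <- function(catalog) {
  if (!length(catalog)) stop("module catalog is empty", call. = FALSE)
  ok <- vapply(catalog, inherits, logical(1), what = "module_definition")
  if (!all(ok)) stop("catalog must be a list of module_definition objects",
                     call. = FALSE)
  ids <- vapply(catalog, function(m) m$module_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate module ids in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.coverage_vector <- function(x, ...) {
  cat(sprintf("<coverage_vector> %s: %d modules, mean %.3f\n",
              x$genome_id, length(x$values), mean(x$values)))
  invisible(x)
}

# ---- I/O -------------------------------------------------------------------

#' Load KO annotation profiles from a TSV table
#'
#' Expects a header row and columns `genome_id`, `gene_id`, `ko_id`
#' (the product of an upstream gene-prediction + KO-assignment step).
#' Rows with an empty `ko_id` are unannotated genes and are ignored;
#' duplicate KO assignments within a genome are aggregated into counts.
#'
#' @param path path to the annotation TSV.
#' @return named list of `ko_profile`, one per distinct `genome_id`
#'   (genomes whose genes are all unannotated yield empty profiles).
#' @export
load_ko_annotations <- function(path) {
  df <- read_tsv_strict(path, required = c("genome_id", "gene_id", "ko_id"))
  df$genome_id <- as.character(df$genome_id)
  df$ko_id <- as.character(df$ko_id)
  genomes <- unique(df$genome_id)
  profiles <- lapply(genomes, function(g) {
    kos <- df$ko_id[df$genome_id == g]
    kos <- kos[!is.na(kos) & nzchar(kos)]
    if (!length(kos)) return(ko_profile(g))
    tab <- table(kos)
    ko_profile(g, stats::setNames(as.integer(tab), names(tab)))
  })
  stats::setNames(profiles, genomes)
}

#' Load a module catalog
#'
#' Accepts either a two-column TSV (`module_id`, `definition_text`) or a
#' directory of per-module text files whose stem is the module id and
#' whose first non-empty line is the DEFINITION string.
#'
#' @param path file or directory path.
#' @return list of `module_definition` in file/row order.
#' @export
load_module_catalog <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (!length(files)) stop("no module files in directory: ", path,
                             call. = FALSE)
    defs <- lapply(files, function(f) {
      lines <- readLines(f, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (!length(lines)) stop("empty module file: ", f, call. = FALSE)
      parse_module_definition(tools::file_path_sans_ext(basename(f)),
                              lines[[1]])
    })
  } else {
    df <- read_tsv_strict(path, required = c("module_id", "definition_text"))
    defs <- Map(parse_module_definition,
                as.character(df$module_id), as.character(df$definition_text))
    defs <- unname(defs)
  }
  check_catalog(defs)
  defs
}
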