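#' Select atoms with a small selection grammar
#'
#' The grammar supports the keywords `protein`, `ligand`, `water`, `backbone`
#' (protein N, CA, C, O), `calpha`, `sidechain`, `all`; the fields
#' `residue <n>`, `residue <a>-<b>`, `resname <NAME>`, `name <NAME>`,
#' `chain <ID>`, `element <E>` (fields accept comma-separated lists); and the
#' boolean operators `and`, `or`, `not` with parentheses. Matching of names is
#' case-insensitive.
#'
#' @param topology A [topology()] object.
#' @param expr Selection expression, e.g. `"calpha and residue 10-20"`.
#' @return An integer vector of unique, sorted 1-based atom indices with class
#'   `bindmode_selection`; the expression is kept in the `"expr"` attribute.
#'   An empty result is returned as an empty selection, not an error.
#' @export
select_atoms <- function(topology, expr) {
  tokens <- tokenize_selection(expr)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  state$expr <- expr
  mask <- parse_or(state, topology)
  if (state$pos <= length(state$tokens)) {
    tok <- state$tokens[[state$pos]]
    stop_bindmode(sprintf("selection parse error at position %d ('%s') in \"%s\"",
                          tok$at, tok$text, expr), "bindmode_parse_error")
  }
  idx <- which(mask)
  structure(as.integer(idx), class = "bindmode_selection", expr = expr)
}

#' @export
print.bindmode_selection <- function(x, ...) {
  cat(sprintf("<bindmode_selection> %d atoms from \"%s\"\n", length(x), attr(x, "expr")))
  invisible(x)
}

tokenize_selection <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L) {
    stop_bindmode("selection expression must be a single string", "bindmode_parse_error")
  }
  tokens <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(text = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substring(expr, i), regexpr("^[A-Za-z0-9_',*-]+", substring(expr, i)))
    if (length(m) == 0L) {
      stop_bindmode(sprintf("selection parse error at position %d ('%s') in \"%s\"",
                            i, ch, expr), "bindmode_parse_error")
    }
    tokens[[length(tokens) + 1L]] <- list(text = m, at = i)
    i <- i + nchar(m)
  }
  tokens
}

peek_tok <- function(state) {
  if (state$pos > length(state$tokens)) NULL else state$tokens[[state$pos]]
}

take_tok <- function(state) {
  tok <- peek_tok(state)
  if (is.null(tok)) {
    stop_bindmode(sprintf("selection parse error: unexpected end of \"%s\"", state$expr),
                  "bindmode_parse_error")
  }
  state$pos <- state$pos + 1L
  tok
}

parse_or <- function(state, top) {
  mask <- parse_and(state, top)
  repeat {
    tok <- peek_tok(state)
    if (is.null(tok) || tolower(tok$text) != "or") return(mask)
    take_tok(state)
    mask <- mask | parse_and(state, top)
  }
}

parse_and <- function(state, top) {
  mask <- parse_not(state, top)
  repeat {
    tok <- peek_tok(state)
    if (is.null(tok) || tolower(tok$text) != "and") return(mask)
    take_tok(state)
    mask <- mask & parse_not(state, top)
  }
}

parse_not <- function(state, top) {
  tok <- peek_tok(state)
  if (!is.null(tok) && tolower(tok$text) == "not") {
    take_tok(state)
    return(!parse_not(state, top))
  }
  parse_primary(state, top)
}

parse_primary <- function(state, top) {
  tok <- take_tok(state)
  atoms <- top$atoms
  word <- tolower(tok$text)
  if (word == "(") {
    mask <- parse_or(state, top)
    closing <- take_tok(state)
    if (closing$text != ")") {
      stop_bindmode(sprintf("selection parse error at position %d: expected ')' in \"%s\"",
                            closing$at, state$expr), "bindmode_parse_error")
    }
    return(mask)
  }
  backbone_names <- c("N", "CA", "C", "O")
  switch(word,
    all = rep(TRUE, nrow(atoms)),
    protein = atoms$segment == "protein",
    ligand = atoms$segment == "ligand",
    water = atoms$is_water,
    backbone = atoms$segment == "protein" & atoms$name %in% backbone_names,
    sidechain = atoms$segment == "protein" &
      !(atoms$name %in% c(backbone_names, "H", "HN", "HA", "HA2", "HA3")),
    calpha = atoms$segment == "protein" & atoms$name == "CA",
    residue = ,
    resno = parse_residue_value(state, top, tok),
    resname = {
      v <- toupper(strsplit(take_tok(state)$text, ",")[[1]])
      atoms$resname %in% v
    },
    name = {
      v <- toupper(strsplit(take_tok(state)$text, ",")[[1]])
      toupper(atoms$name) %in% v
    },
    chain = {
      v <- strsplit(take_tok(state)$text, ",")[[1]]
      atoms$chain %in% v
    },
    element = {
      v <- toupper(strsplit(take_tok(state)$text, ",")[[1]])
      atoms$element %in% v
    },
    stop_bindmode(sprintf("selection parse error at position %d: unknown term '%s' in \"%s\"",
                          tok$at, tok$text, state$expr), "bindmode_parse_error")
  )
}

parse_residue_value <- function(state, top, field_tok) {
  tok <- take_tok(state)
  parts <- strsplit(tok$text, ",")[[1]]
  resnos <- integer()
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      rng <- as.integer(strsplit(p, "-")[[1]])
      resnos <- c(resnos, seq(rng[1], rng[2]))
    } else if (grepl("^[0-9]+$", p)) {
      resnos <- c(resnos, as.integer(p))
    } else {
      stop_bindmode(sprintf("selection parse error at position %d: '%s' is not a residue number or range",
                            tok$at, p), "bindmode_parse_error")
    }
  }
  top$atoms$resno %in% resnos
}
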