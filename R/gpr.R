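#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers that states which
#' gene products catalyze a reaction: `AND` connects genes encoding subunits
#' of an enzyme complex (all are required), `OR` connects genes encoding
#' isoforms (any suffices). Internally a rule is an expression tree whose
#' internal nodes are the operators `ALL` (AND semantics) and `ANY` (OR
#' semantics) and whose leaves are gene identifiers.
#'
#' `parse_gpr()` parses a boolean string such as `"(A AND B) OR C"` with the
#' usual precedence (AND binds tighter than OR; parentheses override).
#' Operator keywords are case-insensitive; `&` and `|` are accepted synonyms.
#'
#' @param x A single GPR expression string.
#' @return A `gpr_rule` object.
#' @examples
#' r <- parse_gpr("(HEXA AND HEXB) OR NEU1")
#' gpr_class(r)
#' gpr_genes(r)
#' @export
parse_gpr <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || !nzchar(trimws(x))) {
    abort("GPR expression is empty.", class = "rasnet_gpr_error")
  }
  toks <- gpr_tokenize(x)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  rule <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    abort(
      sprintf("Unexpected token '%s' in GPR expression '%s'.",
              st$toks[st$pos], x),
      class = "rasnet_gpr_error"
    )
  }
  rule
}

gpr_tokenize <- function(x) {
  x <- gsub("&", " AND ", x, fixed = TRUE)
  x <- gsub("|", " OR ", x, fixed = TRUE)
  x <- gsub("(", " ( ", x, fixed = TRUE)
  x <- gsub(")", " ) ", x, fixed = TRUE)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  terms <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && toupper(tk) == "OR") {
    st$pos <- st$pos + 1L
    terms <- c(terms, list(gpr_parse_and(st)))
  }
  if (length(terms) == 1L) terms[[1]] else gpr_node("ANY", terms)
}

gpr_parse_and <- function(st) {
  terms <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && toupper(tk) == "AND") {
    st$pos <- st$pos + 1L
    terms <- c(terms, list(gpr_parse_atom(st)))
  }
  if (length(terms) == 1L) terms[[1]] else gpr_node("ALL", terms)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) {
    abort("GPR expression ended unexpectedly.", class = "rasnet_gpr_error")
  }
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      abort("Unbalanced parentheses in GPR expression.",
            class = "rasnet_gpr_error")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (toupper(tk) %in% c("AND", "OR", ")")) {
    abort(sprintf("Unexpected token '%s' in GPR expression.", tk),
          class = "rasnet_gpr_error")
  }
  st$pos <- st$pos + 1L
  gpr_leaf(tk)
}

gpr_leaf <- function(gene) {
  structure(list(op = "LEAF", gene = gene), class = "gpr_rule")
}

gpr_node <- function(op, children) {
  # flatten nested same-operator children so "A OR B OR C" is one ANY node
  flat <- list()
  for (ch in children) {
    if (ch$op == op) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(op = op, children = flat), class = "gpr_rule")
}

#' @rdname parse_gpr
#' @param rule A `gpr_rule`.
#' @export
gpr_genes <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  if (rule$op == "LEAF") return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes)))
}

#' @rdname parse_gpr
#' @details `gpr_class()` classifies a rule as `"single"` (one gene),
#'   `"AND"` (a flat complex rule), `"OR"` (a flat isoform rule) or
#'   `"nested"` (operators at more than one level).
#' @export
gpr_class <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  if (rule$op == "LEAF") return("single")
  flat <- all(vapply(rule$children, function(ch) ch$op == "LEAF", logical(1)))
  if (!flat) return("nested")
  if (rule$op == "ALL") "AND" else "OR"
}

#' @export
format.gpr_rule <- function(x, ...) {
  deparse_gpr(x)
}

deparse_gpr <- function(rule, parent_op = NULL) {
  if (rule$op == "LEAF") return(rule$gene)
  sep <- if (rule$op == "ALL") " AND " else " OR "
  inner <- paste(
    vapply(rule$children, deparse_gpr, character(1), parent_op = rule$op),
    collapse = sep
  )
  # parenthesize an OR group under AND (and any nested group for clarity)
  if (!is.null(parent_op)) paste0("(", inner, ")") else inner
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> [", gpr_class(x), "] ", format(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR rule over expression values
#'
#' Computes the reaction activity implied by a GPR rule: an `ALL` (AND) node
#' takes the minimum over its children -- the least-expressed subunit limits
#' the complex -- and an `ANY` (OR) node takes the sum -- isoform activities
#' add. A leaf evaluates to the gene's expression value. Evaluation is
#' recursive for nested rules.
#'
#' Expression may be supplied per gene as a named numeric vector (one value
#' per gene) or as a gene x sample matrix, in which case the result is a
#' vector with one activity per sample.
#'
#' @param rule A [gpr_rule][parse_gpr] object.
#' @param expr Named numeric vector, or numeric matrix with gene rownames.
#' @param missing_genes Policy for leaf genes absent from `expr`:
#'   `"zero"` (default) treats them as expression 0 with a warning,
#'   `"error"` aborts.
#' @return A numeric scalar (vector input) or a vector over samples
#'   (matrix input).
#' @examples
#' evaluate_gpr(parse_gpr("A AND B"), c(A = 3, B = 5))  # 3
#' evaluate_gpr(parse_gpr("A OR B"),  c(A = 3, B = 5))  # 8
#' @export
evaluate_gpr <- function(rule, expr, missing_genes = c("zero", "error")) {
  missing_genes <- match.arg(missing_genes)
  stopifnot(inherits(rule, "gpr_rule"))
  if (is.matrix(expr)) {
    lookup <- function(g) {
      if (g %in% rownames(expr)) expr[g, ] else NULL
    }
    zero <- rep(0, ncol(expr))
    if (!is.null(colnames(expr))) names(zero) <- colnames(expr)
  } else {
    stopifnot(is.numeric(expr), !is.null(names(expr)))
    lookup <- function(g) if (g %in% names(expr)) unname(expr[[g]]) else NULL
    zero <- 0
  }
  miss <- setdiff(gpr_genes(rule), if (is.matrix(expr)) rownames(expr) else names(expr))
  if (length(miss) > 0) {
    msg <- sprintf("GPR gene(s) absent from expression: %s",
                   paste(miss, collapse = ", "))
    if (missing_genes == "error") abort(msg, class = "rasnet_missing_gene")
    warn(paste0(msg, "; treated as 0."), class = "rasnet_missing_gene")
  }
  eval_node <- function(nd) {
    if (nd$op == "LEAF") {
      v <- lookup(nd$gene)
      return(if (is.null(v)) zero else v)
    }
    vals <- lapply(nd$children, eval_node)
    if (nd$op == "ALL") Reduce(pmin, vals) else Reduce(`+`, vals)
  }
  eval_node(rule)
}
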