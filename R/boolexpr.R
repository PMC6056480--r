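#' @include AllClasses.R
NULL

# --- expression trees -------------------------------------------------------
# Update rules are stored as R language objects restricted to the gate set
# &, |, ! plus parentheses, gene-symbol leaves and logical constants. R's `&`
# and `|` vectorize, so a rule evaluates on one state or on a whole batch of
# states (list of logical vectors) in a single eval().

.BOOL_OPS <- c("&", "|", "!", "(")

checkBoolExpr <- function(e) {
  if (is.symbol(e)) {
    if (!nzchar(as.character(e))) stop("empty gene symbol in rule")
    return(invisible(TRUE))
  }
  if (is.logical(e) && length(e) == 1L && !is.na(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% .BOOL_OPS)
      stop(sprintf("operator '%s' is not one of &, |, !", op))
    if (op == "!" && length(e) != 2L) stop("NOT takes exactly one argument")
    for (i in seq_along(e)[-1L]) checkBoolExpr(e[[i]])
    return(invisible(TRUE))
  }
  stop(sprintf("invalid leaf of class '%s' in rule", class(e)[1L]))
}

# numeric constants 0/1 are accepted on input and canonicalized to logicals
.canonConstants <- function(e) {
  if (is.numeric(e) && length(e) == 1L && e %in% c(0, 1)) return(e == 1)
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- .canonConstants(e[[i]])
  }
  e
}

parseBoolExpr <- function(text) {
  e <- tryCatch(str2lang(text),
                error = function(err)
                  stop(sprintf("cannot parse rule '%s': %s", text,
                               conditionMessage(err)), call. = FALSE))
  e <- .canonConstants(e)
  checkBoolExpr(e)
  e
}

#' Construct a Boolean update rule
#'
#' @param target gene symbol the rule updates.
#' @param expr rule body: a character string (e.g. \code{"A & !C"}) or an R
#'   language object using \code{&}, \code{|}, \code{!} and parentheses.
#' @return a \linkS4class{BooleanFunction}
#' @examples
#' booleanFunction("B", "A & !C")
#' @export
booleanFunction <- function(target, expr) {
  if (is.character(expr)) expr <- parseBoolExpr(expr)
  expr <- .canonConstants(expr)
  new("BooleanFunction", target = target, expr = expr)
}

#' Genes appearing as leaves of a rule
#' @param fn a BooleanFunction (or bare language object)
#' @return character vector of regulator gene symbols
#' @export
regulatorsOf <- function(fn) {
  e <- if (is(fn, "BooleanFunction")) fn@expr else fn
  sort(unique(all.vars(e)))
}

formatBoolExpr <- function(e)
  paste(deparse(e, width.cutoff = 500L), collapse = " ")

formatRule <- function(fn)
  sprintf("%s, %s", fn@target, formatBoolExpr(fn@expr))

# Evaluate a rule body on an environment of logical vectors (a single state
# or a batch of states in parallel).
evalBoolExpr <- function(e, env) {
  v <- eval(e, envir = env, enclos = baseenv())
  if (is.numeric(v)) v <- v != 0
  v
}

#' Truth table of a rule over a variable set
#'
#' Enumerates all combinations of \code{vars} (defaults to the rule's own
#' regulators) and records the rule output. Used as the canonical comparison
#' between two rules: rules are considered equal when their truth tables over
#' the union of their regulators agree.
#'
#' @param fn BooleanFunction or language object
#' @param vars variables to enumerate (at most 16)
#' @return data.frame with one 0/1 column per variable plus \code{output}
#' @export
truthTable <- function(fn, vars = regulatorsOf(fn)) {
  e <- if (is(fn, "BooleanFunction")) fn@expr else fn
  k <- length(vars)
  if (k > 16L) stop("refusing to enumerate a truth table over more than 16 variables")
  n <- 2L^k
  env <- list()
  for (i in seq_len(k))
    env[[vars[i]]] <- as.logical(bitwAnd(seq_len(n) - 1L, 2L^(i - 1L)))
  out <- evalBoolExpr(e, env)
  if (length(out) == 1L) out <- rep(out, n)
  df <- as.data.frame(lapply(env, as.integer))
  df$output <- as.integer(out)
  df
}

# truth-table equality over the union of the two regulator sets
sameBoolFunction <- function(f1, f2) {
  vars <- sort(union(regulatorsOf(f1), regulatorsOf(f2)))
  if (length(vars) > 16L) stop("regulator union too large to compare")
  if (length(vars) == 0L) {
    e1 <- if (is(f1, "BooleanFunction")) f1@expr else f1
    e2 <- if (is(f2, "BooleanFunction")) f2@expr else f2
    return(isTRUE(evalBoolExpr(e1, list()) == evalBoolExpr(e2, list())))
  }
  identical(truthTable(f1, vars)$output, truthTable(f2, vars)$output)
}

#' Regulator signs implied by a rule
#'
#' Classifies each regulator as an activator (output monotonically
#' non-decreasing in that input, strictly somewhere), an inhibitor
#' (non-increasing), or undefined (non-monotone or inert).
#'
#' @param fn BooleanFunction or language object
#' @return named character vector: activation / inhibition / undefined
#' @export
regulatorSigns <- function(fn) {
  vars <- regulatorsOf(fn)
  if (!length(vars)) return(structure(character(0), names = character(0)))
  tt <- truthTable(fn, vars)
  out <- tt$output
  signs <- character(length(vars))
  for (i in seq_along(vars)) {
    lo <- out[tt[[vars[i]]] == 0L]
    hi <- out[tt[[vars[i]]] == 1L]
    d <- hi - lo
    signs[i] <- if (all(d >= 0L) && any(d > 0L)) "activation"
                else if (all(d <= 0L) && any(d < 0L)) "inhibition"
                else "undefined"
  }
  structure(signs, names = vars)
}

# Build an AND/OR/NOT expression from an explicit truth table (disjunctive
# normal form over the true rows; constants for degenerate tables).
tableToExpr <- function(output, vars) {
  k <- length(vars)
  stopifnot(length(output) == 2L^max(k, 0L))
  if (all(output == 0L)) return(FALSE)
  if (all(output == 1L)) return(TRUE)
  terms <- list()
  for (row in which(output == 1L)) {
    bits <- as.logical(bitwAnd(row - 1L, 2L^(seq_len(k) - 1L)))
    lits <- mapply(function(v, b) {
      if (b) as.symbol(v) else call("!", as.symbol(v))
    }, vars, bits, SIMPLIFY = FALSE)
    terms[[length(terms) + 1L]] <- Reduce(function(a, b) call("&", a, b), lits)
  }
  Reduce(function(a, b) call("|", a, b), terms)
}

# Does the truth table depend on every variable? (essential support)
.allEssential <- function(output, k) {
  if (k == 0L) return(TRUE)
  idx <- seq_len(2L^k) - 1L
  for (i in seq_len(k)) {
    bit <- 2L^(i - 1L)
    lo <- output[bitwAnd(idx, bit) == 0L]
    hi <- output[bitwAnd(idx, bit) != 0L]
    if (identical(lo, hi)) return(FALSE)
  }
  TRUE
}
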