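#' Parse a reaction equation string
#'
#' Grammar: \code{term ("+" term)* ("->"|"<>") term ("+" term)*}, where
#' a term is an optional positive coefficient (integer, decimal, or
#' exact fraction \code{a/b}) followed by a metabolite id.  Left-hand
#' coefficients are negated, right-hand positive; \code{"<>"} marks the
#' reaction reversible.  A metabolite appearing on both sides has its
#' coefficients summed; one side may be empty (exchange drains).
#'
#' @param text equation string, e.g. \code{"A + 2 B -> C"}.
#' @return list with elements \code{stoichiometry} (named numeric) and
#'   \code{reversible} (logical).
#' @examples
#' parseReactionEquation("A + 2 B -> C")
#' parseReactionEquation("A <> B")
#' @export
parseReactionEquation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  arrowAt <- which(toks %in% c("->", "<>"))
  if (length(arrowAt) != 1) {
    bad <- grep("[<>-]{1,2}", toks, value = TRUE)
    stop("equation must contain exactly one arrow '->' or '<>': ", text)
  }
  reversible <- toks[arrowAt] == "<>"
  parseSide <- function(side, sign) {
    st <- numeric(0)
    i <- 1
    expectTerm <- FALSE
    while (i <= length(side)) {
      tok <- side[i]
      if (tok == "+") {
        if (expectTerm || i == 1)
          stop("malformed term in equation: ", text)
        expectTerm <- TRUE
        i <- i + 1
        next
      }
      expectTerm <- FALSE
      coef <- 1
      if (grepl("^[0-9]+(\\.[0-9]+)?$", tok)) {
        coef <- as.numeric(tok)
        i <- i + 1
      } else if (grepl("^[0-9]+/[0-9]+$", tok)) {
        ab <- as.numeric(strsplit(tok, "/")[[1]])
        coef <- ab[1] / ab[2]
        i <- i + 1
      }
      if (i > length(side) || side[i] %in% c("+", "->", "<>"))
        stop("malformed term in equation: ", text)
      id <- side[i]
      if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", id))
        stop("malformed metabolite id '", id, "' in equation: ", text)
      st[id] <- (if (is.na(st[id])) 0 else st[id]) + sign * coef
      i <- i + 1
    }
    if (expectTerm) stop("malformed term in equation: ", text)
    st
  }
  lhs <- parseSide(toks[seq_len(arrowAt - 1)], -1)
  rhs <- parseSide(toks[seq_len(length(toks) - arrowAt) + arrowAt], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (is.na(st[id])) 0 else st[id]) + rhs[id]
  st <- st[abs(st) > 0]
  if (!length(st))
    stop("zero net coefficient for all species in equation: ", text)
  list(stoichiometry = st, reversible = reversible)
}

#' Serialize a stoichiometry map back to an equation string
#'
#' Inverse of [parseReactionEquation()]: negative coefficients go to
#' the left-hand side, positive to the right; coefficient 1 is omitted.
#'
#' @param stoichiometry named numeric vector.
#' @param reversible logical; emits \code{"<>"} when TRUE else
#'   \code{"->"}.
#' @return equation string.
#' @export
buildReactionEquation <- function(stoichiometry, reversible = FALSE) {
  st <- stoichiometry[stoichiometry != 0]
  fmtTerm <- function(id, coef) {
    if (abs(coef - 1) < 1e-15) id
    else paste(format(coef, digits = 15, scientific = FALSE, trim = TRUE),
               id)
  }
  lhs <- names(st)[st < 0]
  rhs <- names(st)[st > 0]
  l <- paste(mapply(fmtTerm, lhs, -st[lhs]), collapse = " + ")
  r <- paste(mapply(fmtTerm, rhs, st[rhs]), collapse = " + ")
  arrow <- if (reversible) "<>" else "->"
  trimws(paste(l, arrow, r))
}

## Chemical formula codec for the elemental compositions.

#' @noRd
.parseFormula <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(s))
    stop("unparseable formula: ", s)
  el <- sub("[0-9]*$", "", parts)
  ct <- sub("^[A-Za-z]+", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  tapply(ct, el, sum)[unique(el)]
}

#' @noRd
.formatFormula <- function(v) {
  v <- v[v != 0]
  if (!length(v)) return("")
  ord <- order(names(v))
  paste0(names(v)[ord],
         ifelse(v[ord] == 1, "", format(v[ord], trim = TRUE)),
         collapse = "")
}
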