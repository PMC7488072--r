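## JSON network specification:
##   {"genes":  [{"name", "lambda_plus", "lambda_minus", "mu"}, ...],
##    "edges":  [{"source", "target", "sign": "+"|"-", "prob"}, ...]}
## prob may be a string "1/3" for an exact rational; departure d is implied.

.parseProb <- function(p, where) {
  if (is.numeric(p)) return(p)
  if (is.character(p)) {
    if (grepl("^\\s*[0-9.]+\\s*/\\s*[0-9.]+\\s*$", p)) {
      parts <- as.numeric(strsplit(p, "/")[[1]])
      return(parts[1] / parts[2])
    }
    pn <- suppressWarnings(as.numeric(p))
    if (!is.na(pn)) return(pn)
  }
  stop("cannot parse probability '", p, "' in ", where)
}

## render a probability back as "n/d" when it is a simple rational,
## so exact fractions survive a write/read round trip
.formatProb <- function(p) {
  for (den in 2:12) {
    num <- round(p * den)
    if (num >= 1 && num < den && identical(num / den, p))
      return(sprintf("%d/%d", as.integer(num), as.integer(den)))
  }
  p
}

#' Read / write a network specification file
#'
#' The on-disk format is a JSON document with a `genes` array (name and the
#' three rates per gene) and an `edges` array (source, target, sign, prob).
#' Probabilities may be written as strings like `"1/3"` to keep exact
#' rationals; `writeNetwork()` emits such strings automatically for simple
#' fractions, so write-then-read is the identity.
#'
#' @param path file path.
#' @param net a [GeneNetwork-class].
#' @return `readNetwork()` returns a validated [GeneNetwork-class];
#'   `writeNetwork()` returns `path` invisibly.
#' @export
readNetwork <- function(path) {
  spec <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop("cannot parse network spec '",
                                            path, "': ", conditionMessage(e)))
  if (is.null(spec$genes)) stop("network spec '", path, "' is missing key 'genes'")
  g <- vapply(spec$genes, function(x) {
    if (is.null(x$name)) stop("a gene entry in '", path, "' is missing 'name'")
    as.character(x$name)
  }, character(1))
  num <- function(key) vapply(spec$genes, function(x) {
    if (is.null(x[[key]])) stop("gene '", x$name, "' is missing '", key, "'")
    as.numeric(x[[key]])
  }, numeric(1))
  lp <- num("lambda_plus"); lm <- num("lambda_minus"); mu <- num("mu")
  n <- length(g)
  pp <- matrix(0, n, n); pm <- matrix(0, n, n)
  for (e in spec$edges) {
    for (key in c("source", "target", "sign", "prob"))
      if (is.null(e[[key]])) stop("an edge in '", path, "' is missing '", key, "'")
    si <- match(e$source, g); ti <- match(e$target, g)
    if (is.na(si)) stop("edge source '", e$source, "' is not a declared gene")
    if (is.na(ti)) stop("edge target '", e$target, "' is not a declared gene")
    p <- .parseProb(e$prob, sprintf("edge %s -> %s", e$source, e$target))
    if (e$sign == "+") pp[si, ti] <- p
    else if (e$sign == "-") pm[si, ti] <- p
    else stop("edge sign must be '+' or '-', got '", e$sign, "'")
  }
  net <- GeneNetwork(g, lp, lm, mu, pp, pm, validate = FALSE)
  v <- validateNetwork(net)
  if (length(v)) stop("network spec '", path, "' is invalid:\n  ",
                      paste(v, collapse = "\n  "))
  net
}

#' @rdname readNetwork
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  g <- net@geneNames
  genes <- lapply(seq_along(g), function(i) list(
    name = g[i],
    lambda_plus = unname(net@lambdaPlus[i]),
    lambda_minus = unname(net@lambdaMinus[i]),
    mu = unname(net@mu[i])))
  ev <- syncEvents(net)
  edges <- lapply(seq_len(nrow(ev)), function(r) list(
    source = ev$masterName[r], target = ev$slaveName[r], sign = ev$sign[r],
    prob = .formatProb(if (ev$sign[r] == "+") net@pPlus[ev$master[r], ev$slave[r]]
                       else net@pMinus[ev$master[r], ev$slave[r]])))
  ## 17 significant digits guarantee an exact double round trip
  jsonlite::write_json(list(genes = genes, edges = edges), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a table of mean expression levels
#'
#' Expects a TSV with columns `gene`, `condition`, `mean`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("expression table '", path,
                         "' is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$mean < 0)) stop("expression means must be nonnegative")
  df[need]
}
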