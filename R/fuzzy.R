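# Mamdani fuzzy inference for fall detection: linguistic variables with
# piecewise-linear terms, a small IF-THEN rule DSL, min/max inference with
# clipping implication and centroid defuzzification.

# ---- membership functions ---------------------------------------------------

# A membership function is a piecewise-linear curve over strictly increasing
# breakpoints; evaluation clamps to the end values outside them.
fuzzy_mf <- function(x, mu) {
  if (length(x) != length(mu) || length(x) < 2)
    stop_fw("a membership function needs >= 2 (x, mu) breakpoints")
  if (any(diff(x) <= 0)) stop_fw("breakpoint x values must strictly increase")
  if (any(mu < 0 | mu > 1)) stop_fw("memberships must lie in [0, 1]")
  structure(list(x = x, mu = mu), class = "fuzzy_mf")
}

mf_eval <- function(mf, v) approx(mf$x, mf$mu, xout = v, rule = 2)$y

# ---- linguistic variables ---------------------------------------------------

fuzzy_var <- function(name, lo, hi, terms = list(), kind = "continuous") {
  structure(list(name = name, lo = lo, hi = hi, terms = terms, kind = kind),
            class = "fuzzy_var")
}

# Shared LOW/MEDIUM/HIGH shapes for the two velocity ratios. Supports: LOW
# [0, 0.35], MEDIUM [0.25, 0.65], HIGH [0.6, 1.25]; MEDIUM is a symmetric
# triangle, edge terms are shoulders flat toward the domain edge.
velocity_terms <- function() list(
  LOW    = fuzzy_mf(c(0, 0.25, 0.35), c(1, 1, 0)),
  MEDIUM = fuzzy_mf(c(0.25, 0.45, 0.65), c(0, 1, 0)),
  HIGH   = fuzzy_mf(c(0.60, 0.65, 1.25), c(0, 1, 1))
)

default_variables <- function() {
  list(
    WidthToHeightRatio = fuzzy_var("WidthToHeightRatio", 0, 6, list(
      LOW    = fuzzy_mf(c(0, 0.7, 0.8), c(1, 1, 0)),
      MEDIUM = fuzzy_mf(c(0.7, 1.6, 2.5), c(0, 1, 0)),
      HIGH   = fuzzy_mf(c(2.1, 2.5, 6.0), c(0, 1, 1))
    )),
    # A 30% height loss over one fall time corresponds to an initial/final
    # ratio of about 1 / 0.7 ~ 1.43, placed on the HIGH plateau.
    HeightChange = fuzzy_var("HeightChange", 0, 2.5, list(
      LOW    = fuzzy_mf(c(0, 1.05, 1.10), c(1, 1, 0)),
      MEDIUM = fuzzy_mf(c(1.05, 1.20, 1.35), c(0, 1, 0)),
      HIGH   = fuzzy_mf(c(1.30, 1.40, 2.5), c(0, 1, 1))
    )),
    HorizontalVelocity = fuzzy_var("HorizontalVelocity", 0, 1.25,
                                   velocity_terms()),
    VerticalVelocity = fuzzy_var("VerticalVelocity", 0, 1.25,
                                 velocity_terms()),
    FallDirection = fuzzy_var("FallDirection", 0, 1, kind = "crisp"),
    PositionChange = fuzzy_var("PositionChange", 0, 1, kind = "crisp"),
    Fall = fuzzy_var("Fall", 0, 100, list(
      NO  = fuzzy_mf(c(0, 22.5, 45), c(0, 1, 0)),
      YES = fuzzy_mf(c(35, 67.5, 100), c(0, 1, 0))
    ))
  )
}

# indicator column -> linguistic variable
INDICATOR_VARS <- c(whr = "WidthToHeightRatio", height_change = "HeightChange",
                    h_vel = "HorizontalVelocity", v_vel = "VerticalVelocity",
                    direction = "FallDirection",
                    position_change = "PositionChange")

# ---- rule DSL ---------------------------------------------------------------

#' Parse fall-detection rules
#'
#' Grammar, one rule per line (keywords case-insensitive, `#` comments):
#' \preformatted{IF <var> IS [NOT] <term> {AND <var> IS [NOT] <term>} THEN Fall IS <term>}
#' Crisp variables (`FallDirection`, `PositionChange`) take `<var> IS 0` or
#' `<var> IS 1`. Every variable and term is validated against the system's
#' definitions; errors name the offending line.
#'
#' @param text rule text: a character vector of lines, a single string with
#'   newlines, or a file path.
#' @param variables variable definitions to validate against (defaults to the
#'   built-in system).
#' @return list of rules (class `fall_rules`).
#' @export
parse_rules <- function(text, variables = default_variables()) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  rules <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    m <- regexec("^[Ii][Ff]\\s+(.*)\\s+[Tt][Hh][Ee][Nn]\\s+(.*)$", s)
    parts <- regmatches(s, m)[[1]]
    if (length(parts) != 3)
      stop_fw("rule syntax error on line %d: '%s'", ln, s)
    clauses <- strsplit(parts[2], "\\s+[Aa][Nn][Dd]\\s+")[[1]]
    ante <- lapply(clauses, function(cl) parse_clause(cl, ln, variables))
    cons <- parse_consequent(parts[3], ln, variables)
    rules[[length(rules) + 1]] <-
      list(antecedents = ante, consequent = cons, line = ln)
  }
  if (length(rules) == 0) stop_fw("empty rule base")
  structure(rules, class = "fall_rules")
}

parse_clause <- function(cl, ln, variables) {
  m <- regexec("^(\\w+)\\s+[Ii][Ss]\\s+([Nn][Oo][Tt]\\s+)?(\\w+)$",
               trimws(cl))
  parts <- regmatches(trimws(cl), m)[[1]]
  if (length(parts) != 4)
    stop_fw("clause syntax error on line %d: '%s'", ln, cl)
  var <- parts[2]; negated <- parts[3] != ""; term <- parts[4]
  if (!var %in% names(variables))
    stop_fw("line %d: unknown variable '%s'", ln, var)
  v <- variables[[var]]
  if (v$kind == "crisp") {
    if (negated) stop_fw("line %d: NOT is not allowed on crisp '%s'", ln, var)
    if (!term %in% c("0", "1"))
      stop_fw("line %d: crisp '%s' takes 0 or 1, got '%s'", ln, var, term)
    return(list(var = var, value = as.integer(term)))
  }
  if (!term %in% names(v$terms))
    stop_fw("line %d: unknown term '%s' for variable '%s'", ln, term, var)
  list(var = var, term = term, negated = negated)
}

parse_consequent <- function(txt, ln, variables) {
  m <- regexec("^(\\w+)\\s+[Ii][Ss]\\s+(\\w+)$", trimws(txt))
  parts <- regmatches(trimws(txt), m)[[1]]
  if (length(parts) != 3)
    stop_fw("consequent syntax error on line %d: '%s'", ln, txt)
  var <- parts[2]; term <- parts[3]
  if (var != "Fall")
    stop_fw("line %d: consequent variable must be Fall, got '%s'", ln, var)
  if (!term %in% names(variables$Fall$terms))
    stop_fw("line %d: unknown Fall term '%s'", ln, term)
  list(var = var, term = term)
}

# ---- the inference system ---------------------------------------------------

#' Build the fall-detection fuzzy inference system
#'
#' Assembles the six input linguistic variables (WidthToHeightRatio,
#' HeightChange, HorizontalVelocity, VerticalVelocity and the crisp
#' FallDirection, PositionChange), the Fall output (terms NO over \[0, 45\]
#' and YES over \[35, 100\]) and a rule base. The packaged reference rules
#' capture the behaviour the detector is built around: a large height change
#' with non-negligible velocity, a lying-shaped box after a non-trivial
#' height change, or a lying-shaped box whose corner rose, all vote YES;
#' windows with no height change, or moderate change at low velocities and a
#' non-lying box, vote NO.
#'
#' @param rules a rule file path, rule text, or a parsed `fall_rules` object;
#'   `NULL` loads the packaged reference rule base.
#' @param crossover fall decision threshold on the defuzzified score
#'   (`is_fall = score > crossover`); default 40, the midpoint of the NO/YES
#'   overlap \[35, 45\].
#' @param step defuzzification grid step over \[0, 100\].
#' @return an object of class `fall_fis`.
#' @examples
#' fis <- fall_system()
#' iv <- data.frame(whr = 1.75, height_change = 1.40, h_vel = 0.087,
#'                  v_vel = 0.610, direction = 0, position_change = 0)
#' predict(fis, iv)
#' @export
fall_system <- function(rules = NULL, crossover = 40, step = 0.05) {
  variables <- default_variables()
  if (is.null(rules))
    rules <- system.file("rules", "reference.rules", package = "fallwatch",
                         mustWork = TRUE)
  if (!inherits(rules, "fall_rules")) rules <- parse_rules(rules, variables)
  structure(list(variables = variables, rules = rules,
                 crossover = crossover, step = step),
            class = "fall_fis")
}

#' @export
print.fall_fis <- function(x, ...) {
  n_in <- sum(names(x$variables) != "Fall")
  cat(sprintf("<fall_fis: %d input variables, %d rules, crossover %g>\n",
              n_in, length(x$rules), x$crossover))
  invisible(x)
}

#' @export
summary.fall_fis <- function(object, ...) {
  cat("Mamdani fall-detection system\n")
  for (v in object$variables) {
    if (v$kind == "crisp") {
      cat(sprintf("  %s: crisp {0, 1}\n", v$name))
    } else {
      supp <- vapply(names(v$terms), function(t) {
        mf <- v$terms[[t]]
        sprintf("%s[%g..%g]", t, min(mf$x), max(mf$x))
      }, character(1))
      cat(sprintf("  %s in [%g, %g]: %s\n", v$name, v$lo, v$hi,
                  paste(supp, collapse = " ")))
    }
  }
  cat(sprintf("  %d rules; AND = min, implication = clip, aggregation = max,\n",
              length(object$rules)))
  cat(sprintf("  centroid defuzzification on a %g-step grid; fall when score > %g\n",
              object$step, object$crossover))
  invisible(object)
}

#' Plot the membership functions of the system
#'
#' One panel per continuous variable, each term as a piecewise-linear curve.
#'
#' @param x a `fall_fis`.
#' @param ... unused.
#' @export
plot.fall_fis <- function(x, ...) {
  cont <- Filter(function(v) v$kind != "crisp", x$variables)
  op <- graphics::par(mfrow = c(ceiling(length(cont) / 2), 2),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in cont) {
    grid <- seq(v$lo, v$hi, length.out = 400)
    graphics::plot(NULL, xlim = c(v$lo, v$hi), ylim = c(0, 1.05),
                   xlab = v$name, ylab = expression(mu), main = v$name)
    for (i in seq_along(v$terms)) {
      graphics::lines(grid, mf_eval(v$terms[[i]], grid), col = i, lwd = 2)
    }
    graphics::legend("right", legend = names(v$terms), col = seq_along(v$terms),
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(x)
}

iv_value <- function(iv, var) {
  col <- names(INDICATOR_VARS)[INDICATOR_VARS == var]
  as.numeric(iv[[col]][1])
}

#' Fuzzify an indicator row
#'
#' Clamps each continuous indicator into its variable's domain and evaluates
#' every term's membership; crisp indicators pass through.
#'
#' @param fis a [fall_system()].
#' @param iv one-row data frame with the six indicator columns
#'   (`whr, height_change, h_vel, v_vel, direction, position_change`).
#' @return named list: per continuous variable a named vector of term
#'   memberships, per crisp variable its 0/1 value.
#' @export
fuzzify <- function(fis, iv) {
  out <- list()
  for (v in fis$variables) {
    if (v$name == "Fall") next
    val <- iv_value(iv, v$name)
    if (!is.finite(val)) stop_fw("indicator for %s is not finite", v$name)
    if (v$kind == "crisp") {
      out[[v$name]] <- as.integer(val)
    } else {
      val <- clamp(val, v$lo, v$hi)
      out[[v$name]] <- vapply(v$terms, mf_eval, numeric(1), v = val)
    }
  }
  out
}

rule_activation <- function(rule, memberships) {
  mus <- vapply(rule$antecedents, function(cl) {
    if (!is.null(cl$value))
      return(as.numeric(memberships[[cl$var]] == cl$value))
    mu <- memberships[[cl$var]][[cl$term]]
    if (cl$negated) 1 - mu else mu
  }, numeric(1))
  min(mus)
}

#' Mamdani inference to the fall score
#'
#' Activates each rule by the minimum of its clause memberships (negated
#' clauses use `1 - mu`), aggregates per output term by maximum, clips each
#' Fall term at its aggregate activation, unions the clipped shapes
#' pointwise, and returns the centroid of the aggregate computed by the
#' trapezoid rule on a uniform grid over \[0, 100\]. Returns 0 when no rule
#' activates.
#'
#' @inheritParams fuzzify
#' @param step grid step override (defaults to the system's).
#' @return the defuzzified fall score in \[0, 100\].
#' @export
infer_fall <- function(fis, iv, step = NULL) {
  if (is.null(step)) step <- fis$step
  memberships <- fuzzify(fis, iv)
  act <- numeric(0)
  for (rule in fis$rules) {
    a <- rule_activation(rule, memberships)
    term <- rule$consequent$term
    act[term] <- max(a, if (term %in% names(act)) act[term] else 0)
  }
  if (length(act) == 0 || max(act) == 0) return(0)
  out <- fis$variables$Fall
  grid <- seq(out$lo, out$hi, by = step)
  agg <- rep(0, length(grid))
  for (term in names(act)) {
    if (act[term] == 0) next
    agg <- pmax(agg, pmin(mf_eval(out$terms[[term]], grid), act[term]))
  }
  area <- trapz(grid, agg)
  if (area == 0) return(0)
  trapz(grid, grid * agg) / area
}

#' Fall decision from the score
#'
#' @param score defuzzified fall score in \[0, 100\].
#' @param crossover decision threshold (exclusive); default 40, the midpoint
#'   of the NO/YES term overlap.
#' @return logical: `TRUE` when the score indicates a fall.
#' @export
decide_fall <- function(score, crossover = 40) {
  score > crossover
}

#' Fall-pattern label
#'
#' Crisp decision tree over the indicators, applied only after a positive
#' fall decision (otherwise the label is 0):
#' 1. a risen corner (`position_change = 1`) with a clearly lying final box
#'    (`mu_HIGH(whr) > 0.5`) is a fall from a lying position — label 7;
#' 2. otherwise the origin is *standing* when the height change is at least
#'    as HIGH as MEDIUM, else *sitting*;
#' 3. `direction = 1` selects a lateral-right fall (standing 2, sitting 5);
#'    `direction = 0` a backward/forward fall (standing 1, sitting 4).
#'
#' Labels 3 and 6 (lateral-left) require the optional signed horizontal
#' displacement `dx` (pixels, negative = leftward): when supplied and
#' negative, lateral falls are labelled left instead of right.
#'
#' @inheritParams fuzzify
#' @param is_fall logical fall decision for the window.
#' @param dx optional signed horizontal displacement of the box corner.
#' @return integer label in `0..7` (0 = no fall).
#' @export
classify_pattern <- function(fis, iv, is_fall, dx = NULL) {
  if (!isTRUE(is_fall)) return(0L)
  memberships <- fuzzify(fis, iv)
  whr_mu <- memberships$WidthToHeightRatio
  hc_mu <- memberships$HeightChange
  if (memberships$PositionChange == 1 && whr_mu[["HIGH"]] > 0.5) return(7L)
  standing <- hc_mu[["HIGH"]] >= hc_mu[["MEDIUM"]]
  lateral <- memberships$FallDirection == 1 || (!is.null(dx) && dx < 0)
  left <- !is.null(dx) && dx < 0
  if (!lateral) return(if (standing) 1L else 4L)
  if (left) return(if (standing) 3L else 6L)
  if (standing) 2L else 5L
}

#' Score, decide and classify indicator rows
#'
#' @param object a [fall_system()].
#' @param newdata data frame of indicator rows (columns
#'   `whr, height_change, h_vel, v_vel, direction, position_change`; extra
#'   columns such as `window` are carried through).
#' @param ... unused.
#' @return `newdata` with columns `score`, `is_fall` and `pattern` appended.
#' @export
predict.fall_fis <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  n <- nrow(newdata)
  score <- numeric(n); fall <- logical(n); pattern <- integer(n)
  for (i in seq_len(n)) {
    iv <- newdata[i, , drop = FALSE]
    score[i] <- infer_fall(object, iv)
    fall[i] <- decide_fall(score[i], object$crossover)
    pattern[i] <- classify_pattern(object, iv, fall[i])
  }
  cbind(newdata, data.frame(score = score, is_fall = fall, pattern = pattern))
}
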