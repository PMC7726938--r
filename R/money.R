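#' Round a monetary amount half-up
#'
#' Spreadsheet-style rounding to cents: exact halves round away from zero,
#' unlike [round()] (banker's rounding). All internal model arithmetic is
#' carried at full double precision; this function is applied only where a
#' value crosses into a report, a serialized file, or a printed breakdown.
#'
#' @param x numeric vector of amounts in BRL.
#' @param digits number of decimal places to keep (default 2, i.e. cents).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_brl(c(2.345, 2.344, -2.345))
#' @export
round_brl <- function(x, digits = 2) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  s <- abs(x) * p
  # nudge compensates binary representation error just below an exact half
  s <- s * (1 + 8 * .Machine$double.eps)
  sign(x) * floor(s + 0.5) / p
}

#' Parse a currency string in Brazilian or ISO format
#'
#' Accepts amounts written either Brazilian style (`"15.809,57"`) or ISO
#' style (`"15,809.57"`), with or without an `R$` prefix and surrounding
#' whitespace. Official Brazilian sources mix both conventions, so the
#' reader normalizes rather than assuming one locale.
#'
#' @param x character vector of currency strings (plain numbers also pass).
#' @return numeric vector in BRL.
#' @examples
#' parse_brl(c("R$ 15.809,57", "15,809.57", "642.34", "1.234"))
#' @export
parse_brl <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- gsub("R\\$| |\\s", "", s)
    if (s == "") return(NA_real_)
    has_dot <- grepl("\\.", s)
    has_com <- grepl(",", s)
    if (has_dot && has_com) {
      # the later separator is the decimal mark
      if (regexpr("\\.[^.]*$", s) > regexpr(",[^,]*$", s)) {
        s <- gsub(",", "", s)                      # ISO: 15,809.57
      } else {
        s <- gsub("\\.", "", s); s <- sub(",", ".", s)  # BR: 15.809,57
      }
    } else if (has_com) {
      # a single comma followed by exactly two digits is a decimal comma
      if (grepl("^[0-9]+,[0-9]{2}$", s)) s <- sub(",", ".", s)
      else s <- gsub(",", "", s)
    } else if (has_dot) {
      # "1.234" (three digits after a single dot) is a BR thousands group
      if (grepl("^[0-9]{1,3}(\\.[0-9]{3})+$", s)) s <- gsub("\\.", "", s)
    }
    out <- suppressWarnings(as.numeric(s))
    if (is.na(out)) stop("unparseable currency string: ", sQuote(s), call. = FALSE)
    out
  }, numeric(1), USE.NAMES = FALSE)
}

#' Format an amount in BRL
#'
#' @param x numeric vector of amounts.
#' @param locale `"iso"` for `1,234.56`, `"br"` for `1.234,56`.
#' @return character vector.
#' @examples
#' format_brl(-8612200, locale = "br")
#' @export
format_brl <- function(x, locale = c("iso", "br")) {
  locale <- match.arg(locale)
  x <- round_brl(x)
  if (locale == "iso") {
    formatC(x, format = "f", digits = 2, big.mark = ",")
  } else {
    formatC(x, format = "f", digits = 2, big.mark = ".", decimal.mark = ",")
  }
}

# ---- calendar year-month helpers (internal) --------------------------------
# Months are "YYYY-MM" strings throughout the public interface; internally an
# integer index (year*12 + month - 1) makes step-function arithmetic trivial.

ym_check <- function(ym) {
  if (!all(grepl("^[0-9]{4}-[0-9]{2}$", ym)))
    stop("year-months must be 'YYYY-MM' strings, got: ",
         paste(utils::head(ym[!grepl("^[0-9]{4}-[0-9]{2}$", ym)], 3), collapse = ", "),
         call. = FALSE)
  m <- as.integer(substr(ym, 6, 7))
  if (any(m < 1 | m > 12)) stop("month component outside 01..12", call. = FALSE)
  invisible(ym)
}

ym_index <- function(ym) {
  ym_check(ym)
  as.integer(substr(ym, 1, 4)) * 12L + as.integer(substr(ym, 6, 7)) - 1L
}

ym_from_index <- function(i) sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)

ym_seq <- function(from, to) {
  a <- ym_index(from); b <- ym_index(to)
  if (b < a) stop("empty year-month range: ", from, " .. ", to, call. = FALSE)
  ym_from_index(seq.int(a, b))
}

# run `code` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
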