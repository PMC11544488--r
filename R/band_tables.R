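# Declarative band tables: each aggregated weighted score is a sum of
# integer subscores looked up from half-open intervals over each vital.
# Tables ship as YAML data files so local variants can be swapped in.

parse_interval <- function(s) {
  m <- regmatches(s, regexec("^\\[\\s*([0-9.eE+-]+|-?inf)\\s*,\\s*([0-9.eE+-]+|inf|\\.inf)\\s*\\)$", s))[[1]]
  if (length(m) != 3) stop("cannot parse interval '", s, "' (expected \"[lo,hi)\")")
  lo <- if (grepl("inf", m[2])) -Inf else as.numeric(m[2])
  hi <- if (grepl("inf", m[3])) Inf else as.numeric(m[3])
  if (!lo < hi) stop("empty interval '", s, "'")
  c(lo = lo, hi = hi)
}

compile_bands <- function(bands, component) {
  iv <- t(vapply(bands, function(b) parse_interval(b$interval), c(lo = 0, hi = 0)))
  pts <- vapply(bands, function(b) as.integer(b$points), integer(1))
  o <- order(iv[, "lo"])
  iv <- iv[o, , drop = FALSE]; pts <- pts[o]
  if (any(pts < 0)) stop("negative subscore in component ", component)
  # disjoint + covering: consecutive intervals must abut exactly
  if (nrow(iv) > 1 && any(abs(iv[-nrow(iv), "hi"] - iv[-1, "lo"]) > 1e-12)) {
    stop("bands for ", component, " are not disjoint and covering")
  }
  list(breaks = c(iv[, "lo"], iv[nrow(iv), "hi"]), points = pts)
}

#' Load a scoring band table
#'
#' Band tables for MEWS, NEWS and NEWS2 are shipped as YAML under
#' `inst/extdata/band_tables/`; a path to a local variant may be given
#' instead of a score name.
#'
#' @param score `"MEWS"`, `"NEWS"`, `"NEWS2"`, or a path to a YAML file.
#' @return A compiled band table (list), class `"band_table"`.
#' @export
load_band_table <- function(score) {
  path <- if (file.exists(score)) {
    score
  } else {
    system.file("extdata", "band_tables",
                paste0(tolower(score), ".yaml"), package = "ewsbench")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("no band table for '", score, "'")
  }
  y <- yaml::read_yaml(path)
  comps <- lapply(names(y$components), function(nm) {
    c0 <- y$components[[nm]]
    if (identical(c0$type, "numeric")) {
      list(name = nm, type = "numeric", table = compile_bands(c0$bands, nm))
    } else if (identical(c0$type, "scaled")) {
      list(name = nm, type = "scaled",
           scales = lapply(c0$scales, function(s) compile_bands(s$bands, nm)))
    } else if (identical(c0$type, "categorical")) {
      list(name = nm, type = "categorical",
           points = unlist(c0$points))
    } else if (identical(c0$type, "boolean")) {
      pts <- unlist(c0$points)
      list(name = nm, type = "boolean",
           true = as.integer(pts[["TRUE"]]), false = as.integer(pts[["FALSE"]]))
    } else {
      stop("unknown component type for ", nm)
    }
  })
  names(comps) <- names(y$components)
  structure(list(score_name = y$score_name, version = y$source_version,
                 components = comps),
            class = "band_table")
}

# vectorised interval lookup; NA values give NA subscore
band_points <- function(compiled, x) {
  idx <- findInterval(x, compiled$breaks, rightmost.closed = FALSE,
                      left.open = FALSE)
  idx[idx < 1 | idx > length(compiled$points)] <- NA_integer_
  out <- compiled$points[idx]
  out[is.na(x)] <- NA_integer_
  out
}
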