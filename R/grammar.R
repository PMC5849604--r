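#' Phene name grammar
#'
#' Phene candidates are identified by short structured names describing the
#' measurement: the operation, its marker argument(s), and the region(s) it
#' is evaluated in. The canonical renderings are
#'
#' * `#CD8_border1` — count of CD8 cells in the tight tumor border;
#' * `DENSITY CD8 IN border1` — the same count per region area (cells/mm^2);
#' * `RATIO #CD8_border1 TO #CD34_border1` — ratio of two counts (regions may
#'   differ);
#' * `DIST CD68 TO CD34 IN nonIntact` — mean distance of CD68 cells inside the
#'   tumor region to their 4 nearest CD34 cells (`DIST8 ...` uses 8
#'   neighbours);
#' * `CORR Haralick on intact & non-intact glands` — co-occurrence texture of
#'   gland classes (`... on intact gland sizes` / `... on non-intact gland
#'   sizes` for the size-class variants).
#'
#' Regions: `nonIntact` (tumor gland region), `intact` (healthy glands),
#' `stroma`, `innerBorder` (56 um each side of the tumor boundary), `border1`
#' (112.5 um outer band), `border2` (225 um outer band), `ws` (whole slide,
#' background excluded).
#'
#' `phene_name()` builds a validated name record; `render_phene()` and
#' `parse_phene()` convert between records and canonical strings and are
#' exact inverses on valid names.
#'
#' @param operation One of `"COUNT"`, `"DENSITY"`, `"RATIO"`, `"DIST"`,
#'   `"CORR_HARALICK"`.
#' @param arg1,arg2 Marker labels (`arg2` only for RATIO/DIST).
#' @param location,location2 Region labels; `location2` only for RATIO.
#' @param k Neighbour count for DIST (4 or 8).
#' @param class_set Gland class set for CORR_HARALICK: one of
#'   `"intact_nonintact"`, `"intact_size"`, `"nonintact_size"`.
#' @return `phene_name()`: a one-row tibble of class `phene_name` with the
#'   parsed fields and the rendered `name`. `render_phene()`: a character
#'   string. `parse_phene()`: a `phene_name` tibble (one row per input).
#' @examples
#' p <- phene_name("RATIO", "CD8", "CD34", location = "border1")
#' render_phene(p)
#' parse_phene("DIST CD68 TO CD34 IN nonIntact")$k
#' @export
phene_name <- function(operation, arg1 = NA, arg2 = NA,
                       location = "ws", location2 = NA,
                       k = 4L, class_set = NA) {
  operation <- match.arg(operation,
                         c("COUNT", "DENSITY", "RATIO", "DIST", "CORR_HARALICK"))
  if (operation == "CORR_HARALICK") {
    class_set <- match.arg(class_set,
                           c("intact_nonintact", "intact_size", "nonintact_size"))
    arg1 <- arg2 <- NA_character_
    location <- "ws"
    location2 <- NA_character_
    k <- NA_integer_
  } else {
    arg1 <- normalize_marker(arg1)
    if (!location %in% .locations) abort(paste0("unknown location: ", location))
    if (operation %in% c("RATIO", "DIST")) {
      arg2 <- normalize_marker(arg2)
    } else {
      arg2 <- NA_character_
    }
    if (operation == "RATIO") {
      location2 <- location2 %||% location
      if (is.na(location2)) location2 <- location
      if (!location2 %in% .locations) abort(paste0("unknown location: ", location2))
    } else {
      location2 <- NA_character_
    }
    if (operation == "DIST") {
      if (!k %in% c(4L, 8L)) abort("DIST supports k = 4 or 8 only")
      k <- as.integer(k)
    } else {
      k <- NA_integer_
    }
    class_set <- NA_character_
  }
  out <- tibble::tibble(
    operation = operation, arg1 = arg1, arg2 = arg2,
    location = location, location2 = location2,
    k = k, class_set = class_set
  )
  out$name <- render_phene(out)
  class(out) <- c("phene_name", class(out))
  out
}

.corr_labels <- c(
  intact_nonintact = "intact & non-intact glands",
  intact_size      = "intact gland sizes",
  nonintact_size   = "non-intact gland sizes"
)

#' @rdname phene_name
#' @param x For `render_phene()`, a `phene_name` record (or data frame of
#'   fields); for `parse_phene()`, a character vector of canonical names.
#' @export
render_phene <- function(x) {
  vapply(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    switch(r$operation,
      COUNT   = paste0("#", r$arg1, "_", r$location),
      DENSITY = paste0("DENSITY ", r$arg1, " IN ", r$location),
      RATIO   = paste0("RATIO #", r$arg1, "_", r$location,
                       " TO #", r$arg2, "_", r$location2),
      DIST    = paste0(if (r$k == 8L) "DIST8 " else "DIST ",
                       r$arg1, " TO ", r$arg2, " IN ", r$location),
      CORR_HARALICK = paste0("CORR Haralick on ", .corr_labels[[r$class_set]])
    )
  }, character(1))
}

#' @rdname phene_name
#' @export
parse_phene <- function(x) {
  one <- function(s) {
    mk <- paste0("(", paste(.markers, collapse = "|"), ")")
    loc <- paste0("(", paste(.locations, collapse = "|"), ")")
    if (grepl("^CORR Haralick on ", s)) {
      lab <- sub("^CORR Haralick on ", "", s)
      cs <- names(.corr_labels)[match(lab, .corr_labels)]
      if (is.na(cs)) abort(paste0("cannot parse phene name: ", s))
      return(phene_name("CORR_HARALICK", class_set = cs))
    }
    m <- regmatches(s, regexec(paste0("^RATIO #", mk, "_", loc,
                                      " TO #", mk, "_", loc, "$"), s))[[1]]
    if (length(m) == 5) {
      return(phene_name("RATIO", m[2], m[4], location = m[3], location2 = m[5]))
    }
    m <- regmatches(s, regexec(paste0("^DIST(8?) ", mk, " TO ", mk,
                                      " IN ", loc, "$"), s))[[1]]
    if (length(m) == 5) {
      return(phene_name("DIST", m[3], m[4], location = m[5],
                        k = if (m[2] == "8") 8L else 4L))
    }
    m <- regmatches(s, regexec(paste0("^DENSITY ", mk, " IN ", loc, "$"), s))[[1]]
    if (length(m) == 3) {
      return(phene_name("DENSITY", m[2], location = m[3]))
    }
    m <- regmatches(s, regexec(paste0("^#", mk, "_", loc, "$"), s))[[1]]
    if (length(m) == 3) {
      return(phene_name("COUNT", m[2], location = m[3]))
    }
    abort(paste0("cannot parse phene name: ", s))
  }
  out <- dplyr::bind_rows(lapply(x, one))
  class(out) <- c("phene_name", class(out))
  out
}
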