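# internal helpers shared across modules

# canonical marker labels; aliases cover exclusive phenotyping exports
# (CD3 denotes CD3+CD8- helper T cells; CD8 the cytotoxic subset)
.markers <- c("CD3", "CD8", "CD68", "CD163", "CD34", "negative")

.marker_aliases <- c(
  "CD3+CD8-"   = "CD3",
  "CD3+CD8−" = "CD3",
  "CD8+"       = "CD8",
  "CD68+"      = "CD68",
  "CD163+"     = "CD163",
  "CD34-vessel" = "CD34"
)

normalize_marker <- function(x) {
  x <- as.character(x)
  hit <- x %in% names(.marker_aliases)
  x[hit] <- .marker_aliases[x[hit]]
  bad <- setdiff(unique(x), .markers)
  if (length(bad) > 0) {
    abort(paste0("unknown marker label(s): ", paste(bad, collapse = ", ")))
  }
  x
}

# measurement locations of the region system (grammar vocabulary)
.locations <- c("nonIntact", "intact", "stroma", "innerBorder",
                "border1", "border2", "ws")

# raw (partitioning) raster labels, in precedence order low -> high
.roi_levels <- c("background", "stroma", "healthy", "border2", "border1",
                 "innerBorder_out", "tumor", "innerBorder_in")

# measurement region -> raw label sets; outer borders are cumulative
# dilation zones (border2 spans the full 225 um band and so contains border1)
.location_labels <- list(
  nonIntact   = c("tumor", "innerBorder_in"),
  intact      = "healthy",
  stroma      = "stroma",
  innerBorder = c("innerBorder_in", "innerBorder_out"),
  border1     = c("innerBorder_out", "border1"),
  border2     = c("innerBorder_out", "border1", "border2"),
  ws          = setdiff(.roi_levels, "background")
)

`%||%` <- rlang::`%||%`

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# polygon area by the shoelace formula (vertices in order, unclosed ok)
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# deterministic sub-seed derivation: one global seed fans out to
# independent per-stage streams without mutating the caller's RNG
derive_seeds <- function(seed, n, labels = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  out <- sample.int(.Machine$integer.max, n)
  if (!is.null(labels)) names(out) <- labels
  out
}

# run code under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# columns of a phene matrix that hold candidate values
phene_cols <- function(df) {
  setdiff(names(df), c("patient_id", "dfs_months", "event"))
}

check_survival_table <- function(df) {
  assert_cols(df, c("patient_id", "dfs_months", "event"), "survival table")
  if (anyNA(df$dfs_months) || any(df$dfs_months <= 0)) {
    abort("dfs_months must be positive and non-missing")
  }
  if (!all(df$event %in% c(0, 1))) abort("event must be 0/1")
  invisible(df)
}
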