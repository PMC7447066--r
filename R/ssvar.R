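## Secondary-structure variation index, per-residue mode, and region
## summaries over 3-class (helix / beta / disordered) series.

SS_CLASS_MAP <- c(H = "helix", G = "helix", I = "helix",
                  E = "beta", B = "beta",
                  T = "disordered", S = "disordered", C = "disordered",
                  " " = "disordered", "~" = "disordered")
SS_CLASSES <- c("helix", "beta", "disordered")

#' Collapse DSSP codes into the three structure classes
#'
#' Helical codes (H, G, I -- alpha, 3-10 and pi helices) map to `"helix"`,
#' strand/bridge (E, B) to `"beta"`, and turn/bend/coil (T, S, C, blank, ~)
#' to `"disordered"`. The mapping is total over legal DSSP letters; any
#' other letter is rejected.
#'
#' @param x A character vector/matrix of DSSP codes, or a `psi_ss_series`.
#' @return Same shape with class labels; for a series, a named list of
#'   per-chain class matrices with the series times as an attribute.
#' @export
classify_codes <- function(x) {
  if (inherits(x, "psi_ss_series")) {
    out <- lapply(x$codes, classify_codes)
    attr(out, "times") <- x$times
    return(out)
  }
  bad <- setdiff(unique(as.vector(x)), names(SS_CLASS_MAP))
  if (length(bad))
    abort("unknown DSSP code(s): ", paste(sQuote(bad), collapse = ", "))
  out <- SS_CLASS_MAP[as.vector(x)]
  if (is.matrix(x)) out <- matrix(out, nrow = nrow(x))
  unname(out)
}

count_changes <- function(classes) {
  ## classes: frames x residues matrix; change events per residue
  f <- nrow(classes)
  colSums(classes[-1L, , drop = FALSE] != classes[-f, , drop = FALSE])
}

#' Secondary-structure variation index
#'
#' For each residue, the number of class-change events between consecutive
#' frames, normalised by the maximum theoretical count (frames - 1, i.e. a
#' change every frame; 1000 for a 1001-frame window). Series from both
#' monomers of every replicate are pooled, and the per-residue mean and
#' standard deviation across the pooled series reported (n = chains x
#' replicates).
#'
#' @param x A `psi_ss_series` or a list of them (replicates).
#' @param window Optional tail fraction passed to [select_window()]
#'   (default: the full series, which is taken to be the analysis window).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Object of class `psi_variation`: list with `summary` (data frame
#'   `resno`, `mean`, `sd`, `n`), `per_series` (residues x series matrix of
#'   normalised variation), `raw` (same shape, integer change counts), and
#'   `max_theoretical`.
#' @export
variation_index <- function(x, window = NULL, sd_type = "sample") {
  series <- if (inherits(x, "psi_ss_series")) list(x) else x
  cols <- list(); raws <- list()
  maxth <- NULL
  for (r in seq_along(series)) {
    s <- series[[r]]
    if (!is.null(window)) s <- select_window(s, window)
    f <- length(s$times)
    if (f < 2L) abort("variation index needs at least 2 frames in the window")
    if (is.null(maxth)) maxth <- f - 1L
    for (ch in names(s$codes)) {
      cl <- classify_codes(s$codes[[ch]])
      raw <- count_changes(cl)
      raws[[paste0("rep", r, ":", ch)]] <- raw
      cols[[paste0("rep", r, ":", ch)]] <- raw / (f - 1L)
    }
  }
  per_series <- do.call(cbind, cols)
  raw <- do.call(cbind, raws)
  summary <- data.frame(
    resno = seq_len(nrow(per_series)),
    mean = rowMeans(per_series),
    sd = apply(per_series, 1, spread_sd, sd_type = sd_type),
    n = ncol(per_series))
  structure(list(summary = summary, per_series = per_series, raw = raw,
                 max_theoretical = maxth),
            class = "psi_variation")
}

#' @export
print.psi_variation <- function(x, ...) {
  cat("psi_variation:", nrow(x$summary), "residues,",
      ncol(x$per_series), "pooled series, max theoretical count",
      x$max_theoretical, "\n")
  invisible(x)
}

#' Per-residue modal secondary-structure class
#'
#' Most frequent class per residue over all frames of all pooled series and
#' chains. Exact ties are broken by the fixed precedence helix > beta >
#' disordered.
#'
#' @inheritParams variation_index
#' @return Data frame with `resno`, `mode`.
#' @export
ss_mode <- function(x, window = NULL) {
  series <- if (inherits(x, "psi_ss_series")) list(x) else x
  counts <- NULL
  for (s in series) {
    if (!is.null(window)) s <- select_window(s, window)
    for (ch in names(s$codes)) {
      cl <- classify_codes(s$codes[[ch]])
      cc <- matrix(vapply(SS_CLASSES, function(k) colSums(cl == k),
                          numeric(ncol(cl))),
                   ncol = length(SS_CLASSES))
      counts <- if (is.null(counts)) cc else counts + cc
    }
  }
  mode <- SS_CLASSES[apply(counts, 1, which.max)]  # which.max: first max wins
  data.frame(resno = seq_len(nrow(counts)), mode = mode,
             stringsAsFactors = FALSE)
}

#' Variation summary over a residue region
#'
#' Total of the pooled per-residue mean variation over an inclusive residue
#' interval, and the per-residue average (total / interval length).
#'
#' @param profile A `psi_variation`.
#' @param interval Inclusive residue interval `c(lo, hi)`.
#' @return List with `interval`, `total`, `per_residue`, `n_residues`.
#' @export
region_summary <- function(profile, interval) {
  s <- profile$summary
  if (interval[1] > interval[2] || interval[1] < min(s$resno) ||
      interval[2] > max(s$resno))
    abort("interval must be a non-empty residue range within the sequence")
  idx <- s$resno >= interval[1] & s$resno <= interval[2]
  total <- sum(s$mean[idx])
  list(interval = as.integer(interval), total = total,
       per_residue = total / sum(idx), n_residues = sum(idx))
}

#' Net variation of the whole dimer
#'
#' Sum of pooled per-residue mean variation over all residues of both
#' chains, and the same quantity renormalised per residue.
#'
#' @param profile A `psi_variation`.
#' @param n_chains Number of chains pooled into the profile (default 2).
#' @return List with `total` and `per_residue`.
#' @export
dimer_net_variation <- function(profile, n_chains = 2L) {
  s <- profile$summary
  total <- n_chains * sum(s$mean)
  list(total = total, per_residue = total / (n_chains * nrow(s)))
}
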