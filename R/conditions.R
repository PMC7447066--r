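## Condition-code registry (disulfide reduction states) and pH-dependent
## protonation assignment.

#' Disulfide reduction condition codes
#'
#' Eight condition codes enumerate every subset of the three native disulfide
#' bonds being reduced: `AI` (all intact), `D1`-`D3` (one bond reduced),
#' `D4`-`D6` (two bonds reduced) and `AR` (all reduced). The three columns
#' give the state of Cys6-Cys99, Cys31-Cys71 and Cys37-Cys68 in that order
#' (`"I"` intact, `"R"` reduced).
#'
#' @return Data frame with columns `code`, `b6_99`, `b31_71`, `b37_68`.
#' @export
condition_codes <- function() {
  data.frame(
    code = c("AI", "D1", "D2", "D3", "D4", "D5", "D6", "AR"),
    b6_99  = c("I", "R", "I", "I", "R", "I", "R", "R"),
    b31_71 = c("I", "I", "R", "I", "R", "R", "I", "R"),
    b37_68 = c("I", "I", "I", "R", "I", "R", "R", "R"),
    stringsAsFactors = FALSE)
}

#' Resolve a condition code into intact and reduced disulfide pairs
#'
#' @param code One of `"AI"`, `"D1"`..`"D6"`, `"AR"`.
#' @return List with elements `code`, `ph`-independent `intact` and `reduced`
#'   (integer pair matrices, subsets of [native_cys_pairs()]).
#' @examples
#' resolve_condition("D5")$reduced  # 31-71 and 37-68
#' @export
resolve_condition <- function(code) {
  tab <- condition_codes()
  if (!is.character(code) || length(code) != 1L || !code %in% tab$code)
    abort("unknown condition code '", paste(code, collapse = ","),
          "'; valid codes: ", paste(tab$code, collapse = ", "))
  states <- unlist(tab[tab$code == code, c("b6_99", "b31_71", "b37_68")])
  pairs <- native_cys_pairs()
  list(code = code,
       intact = pairs[states == "I", , drop = FALSE],
       reduced = pairs[states == "R", , drop = FALSE])
}

#' Assign protonation states at a given pH
#'
#' Categorical protonation map over every titratable residue (Asp, Glu, His,
#' Lys, Arg) plus the chain termini, following rule-based defaults:
#' at pH 3.0 all carboxylates (Asp/Glu, C-terminus) are protonated and
#' neutral while His is protonated and charged; at pH 7.4 the carboxylates
#' are deprotonated (charged), His is neutral, and Lys/Arg stay charged at
#' both pH values. Per-residue overrides let any externally computed pKa set
#' be plugged in; overridden entries are flagged by provenance.
#'
#' The termini rows are bookkeeping only: the pseudo-atom topology carries no
#' terminal OXT/H3 atoms, so termini never enter contact counts.
#'
#' @param top A `psi_topology`.
#' @param ph Either `3.0` or `7.4`.
#' @param overrides Optional named character vector mapping residues to
#'   states; names are residue numbers (`"72"`, applied to both chains) or
#'   chain-qualified (`"A:72"`), values are `"charged"` or `"neutral"`
#'   (`"deprotonated"`/`"protonated"` are accepted synonyms).
#' @return Data frame of class `psi_protonation` with columns `chain`,
#'   `resno`, `resid`, `state` (`"charged"`/`"neutral"`), `provenance`
#'   (`"default-rule"`/`"override"`), and attribute `ph`.
#' @examples
#' top <- make_topology(synthetic_spec())
#' pm <- assign_protonation(top, 3.0)
#' subset(pm, resno %in% c(40, 54, 56, 58) & chain == "A")  # all neutral
#' @export
assign_protonation <- function(top, ph, overrides = NULL) {
  if (!ph %in% c(3.0, 7.4))
    abort("unsupported pH ", ph, "; supported values are 3.0 and 7.4")
  rows <- list()
  for (ch in c("A", "B")) {
    rt <- residue_table(top, ch)
    tt <- rt[rt$resid %in% TITRATABLE_RES, ]
    if (nrow(tt)) {
      state <- ifelse(tt$resid %in% ACIDIC_RES,
                      if (ph == 3.0) "neutral" else "charged",
                      ifelse(tt$resid == "HIS",
                             if (ph == 3.0) "charged" else "neutral",
                             "charged"))  # Lys/Arg charged at both pH
      rows[[length(rows) + 1L]] <-
        data.frame(chain = ch, resno = tt$resno, resid = tt$resid,
                   state = state, provenance = "default-rule",
                   stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = ch, resno = c(0L, -1L), resid = c("NTER", "CTER"),
      state = c("charged", if (ph == 3.0) "neutral" else "charged"),
      provenance = "default-rule", stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      abort("overrides must be a named vector")
    for (key in names(overrides)) {
      val <- normalize_state(overrides[[key]])
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (length(parts) == 2L) {
        chs <- parts[1]; rn <- suppressWarnings(as.integer(parts[2]))
      } else {
        chs <- c("A", "B"); rn <- suppressWarnings(as.integer(parts[1]))
      }
      hit <- map$chain %in% chs & map$resno == rn
      if (is.na(rn) || !any(hit))
        abort("protonation override for nonexistent titratable residue '",
              key, "'")
      acid <- map$resid[hit] %in% ACIDIC_RES
      map$state[hit] <- val$state(acid)
      map$provenance[hit] <- "override"
    }
  }
  structure(map, ph = ph, class = c("psi_protonation", "data.frame"))
}

## map user-facing state words onto charged/neutral; for acids "deprotonated"
## means charged, for bases "protonated" means charged
normalize_state <- function(x) {
  x <- match.arg(x, c("charged", "neutral", "protonated", "deprotonated"))
  list(state = function(is_acid) {
    switch(x,
           charged = "charged", neutral = "neutral",
           deprotonated = ifelse(is_acid, "charged", "neutral"),
           protonated = ifelse(is_acid, "neutral", "charged"))
  })
}
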