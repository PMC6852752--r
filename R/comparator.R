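#' Default originator/biosimilar brand pairing
#'
#' The three molecule pairs under study: Remicade/Inflectra (infliximab),
#' Lantus/Basaglar (insulin glargine) and Neupogen/Grastofil (filgrastim).
#'
#' @return A tibble with columns `molecule`, `originator_brand`,
#'   `biosimilar_brand`.
#' @export
#' @examples
#' default_pairing()
default_pairing <- function() {
  tibble(
    molecule = c("infliximab", "insulin glargine", "filgrastim"),
    originator_brand = c("Remicade", "Lantus", "Neupogen"),
    biosimilar_brand = c("Inflectra", "Basaglar", "Grastofil")
  )
}

#' Match originator and biosimilar products at the form/strength level
#'
#' For each molecule, partitions the originator's `(form, strength)` keys
#' into those the biosimilar also sells (`matched`) and those it does not
#' (`excluded`). Excluded keys are assumed to carry no substitution savings
#' and are dropped from downstream price and savings calculations; their
#' dollars are reported by [collapse_purchases()]. A biosimilar key with no
#' originator counterpart has no reference price and violates the pairing
#' contract, as does a biosimilar record for a molecule absent from the
#' pairing.
#'
#' @param records A validated purchase table (or any table with `molecule`,
#'   `brand`, `role`, `form`, `strength` columns).
#' @param pairing Declared brand pairs, one originator and one biosimilar
#'   brand per molecule; default [default_pairing()].
#' @return A tibble with columns `molecule`, `originator_brand`,
#'   `biosimilar_brand`, `form`, `strength`, `status`
#'   (`"matched"`/`"excluded"`), one row per originator key.
#' @export
#' @examples
#' build_comparator_map(generate_purchases(synth_config(seed = 1)))
build_comparator_map <- function(records, pairing = default_pairing()) {
  records <- as_tibble(records)
  dup <- pairing$molecule[duplicated(pairing$molecule)]
  if (length(dup) > 0) {
    abort(sprintf("pairing declares molecule more than once: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bio <- filter(records, .data$role == "biosimilar")
  unpaired <- setdiff(unique(bio$molecule), pairing$molecule)
  if (length(unpaired) > 0) {
    abort(sprintf("biosimilar records for molecule(s) absent from the pairing: %s",
                  paste(unpaired, collapse = ", ")))
  }
  keys <- records |>
    inner_join(pairing, by = "molecule") |>
    filter((.data$role == "originator" & .data$brand == .data$originator_brand) |
             (.data$role == "biosimilar" & .data$brand == .data$biosimilar_brand)) |>
    distinct(.data$molecule, .data$originator_brand, .data$biosimilar_brand,
             .data$role, .data$form, .data$strength)

  orig_keys <- filter(keys, .data$role == "originator")
  bio_keys <- filter(keys, .data$role == "biosimilar")

  orphan <- anti_join(bio_keys, orig_keys,
                      by = c("molecule", "form", "strength"))
  if (nrow(orphan) > 0) {
    abort(sprintf(
      "biosimilar (form, strength) key(s) with no originator counterpart: %s",
      paste(sprintf("%s %s/%s", orphan$molecule, orphan$form, orphan$strength),
            collapse = "; ")))
  }

  orig_keys |>
    mutate(status = ifelse(
      paste(.data$molecule, .data$form, .data$strength) %in%
        paste(bio_keys$molecule, bio_keys$form, bio_keys$strength),
      "matched", "excluded")) |>
    select("molecule", "originator_brand", "biosimilar_brand",
           "form", "strength", "status") |>
    arrange(.data$molecule, .data$form, .data$strength)
}
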