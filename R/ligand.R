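# ligand-efficiency metrics: binding energy per heavy (non-hydrogen) atom

#' Count heavy atoms in a molecular formula
#'
#' Parses a Hill-style molecular formula (element symbol followed by an
#' optional positive count, e.g. `"C18H32O2"`) and returns the number of
#' non-hydrogen atoms. Hydrogen and its isotopic symbols D and T are
#' excluded; charges and isotope labels are not supported.
#'
#' @param formula character vector of molecular formulas.
#' @return Integer vector of heavy-atom counts.
#' @examples
#' heavy_atom_count(c("H2O", "C18H32O2", "C32H42O4"))
#' @export
heavy_atom_count <- function(formula) {
  vapply(formula, function(f) {
    if (!is.character(f) || is.na(f) || !nzchar(f)) {
      abort_micellr("formula must be a non-empty string",
                    "micellr_format_error")
    }
    m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f) || length(tokens) == 0L) {
      abort_micellr(sprintf("cannot parse formula '%s'", f),
                    "micellr_format_error")
    }
    total <- 0L
    for (tok in tokens) {
      elem <- sub("[0-9]*$", "", tok)
      cnt_str <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
      if (is.na(cnt) || cnt == 0L) {
        abort_micellr(sprintf("zero or invalid count in token '%s' of '%s'",
                              tok, f), "micellr_format_error")
      }
      if (!elem %in% c("H", "D", "T")) total <- total + cnt
    }
    if (total < 1L) {
      abort_micellr(sprintf("formula '%s' has no heavy atoms", f),
                    "micellr_format_error")
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

#' Ligand efficiency: binding energy per heavy atom
#'
#' Normalises a binding energy (kcal/mol, more negative = stronger, as in
#' end-point MM-GBSA estimates) by the guest's heavy-atom count, giving a
#' size-corrected affinity metric that allows fair comparison of guests of
#' different molecular size. Summaries round to 3 decimals (half away from
#' zero); full precision is retained in `le`.
#'
#' @param formula molecular formula(s) of the guest(s).
#' @param binding_energy matched binding energies (kcal/mol).
#' @param name optional guest names.
#' @return A tibble with columns `name`, `formula`, `binding_energy`,
#'   `heavy_atoms`, `le` (kcal/mol per heavy atom) and `le_rounded`
#'   (3 decimals).
#' @examples
#' ligand_efficiency("C18H32O2", -47.24, name = "LA")
#' @export
ligand_efficiency <- function(formula, binding_energy, name = formula) {
  if (anyNA(binding_energy) || !is.numeric(binding_energy)) {
    abort_micellr("`binding_energy` must be numeric without NA",
                  "micellr_input_error")
  }
  if (length(formula) != length(binding_energy)) {
    abort_micellr("`formula` and `binding_energy` lengths differ",
                  "micellr_input_error")
  }
  ha <- heavy_atom_count(formula)
  le <- binding_energy / ha
  tibble::tibble(
    name = rep_len(name, length(formula)),
    formula = formula,
    binding_energy = binding_energy,
    heavy_atoms = ha,
    le = le,
    le_rounded = round_half_away(le, 3L)
  )
}

#' Rank guest molecules by raw binding energy or ligand efficiency
#'
#' Orders guests ascending in the chosen metric (most negative, i.e.
#' strongest, first). Ties preserve input order.
#'
#' @param guests a tibble/data.frame with columns `name`, `formula`,
#'   `binding_energy` (kcal/mol), e.g. [guest_fixtures()].
#' @param metric `"energy"` (raw binding energy) or `"le"` (ligand
#'   efficiency).
#' @return The [ligand_efficiency()] table sorted by the chosen metric,
#'   with a `rank` column.
#' @export
rank_guests <- function(guests, metric = c("energy", "le")) {
  metric <- match.arg(metric)
  if (NROW(guests) == 0L) {
    out <- ligand_efficiency(character(), numeric(), character())
    out$rank <- integer()
    return(out)
  }
  if (!all(c("name", "formula", "binding_energy") %in% names(guests))) {
    abort_micellr("`guests` needs columns name, formula, binding_energy",
                  "micellr_input_error")
  }
  tab <- ligand_efficiency(guests$formula, guests$binding_energy,
                           name = guests$name)
  key <- if (metric == "energy") tab$binding_energy else tab$le
  ord <- order(key)  # stable in R
  out <- tab[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Reference guest molecules of the complexation study
#'
#' The six guests considered for inclusion in HP-beta-cyclodextrin -- the
#' free fatty acids linoleic acid (LA) and docosahexaenoic acid (DHA),
#' resveratrol, its two lipophenol esters (esterification condenses out one
#' H2O), and the fluorescent probe diphenylhexatriene (DPHT) -- with their
#' molecular formulas (derived from the standard structures) and reported
#' MM-GBSA binding energies (kcal/mol).
#'
#' @return A tibble with columns `name`, `formula`, `binding_energy`.
#' @export
guest_fixtures <- function() {
  tibble::tibble(
    name = c("LA", "DHA", "resveratrol", "Resv-4'-LA", "Resv-4'-DHA", "DPHT"),
    formula = c("C18H32O2", "C22H32O2", "C14H12O3", "C32H42O4", "C36H42O4",
                "C18H16"),
    binding_energy = c(-47.24, -51.05, -45.52, -64.36, -58.34, -47.38)
  )
}
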