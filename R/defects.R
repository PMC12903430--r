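#' Composition of a defect variant
#'
#' Mass-spectrometric characterisation of capped dendrimers reads
#' structural completeness from ladders of species offset from the perfect
#' mass.  Two defect kinds are modelled, composing additively:
#'
#' * a **missing cap**: one peripheral allyl that never reacted in the
#'   thiol-ene step, removing exactly one cap composition;
#' * a **missing branch** at layer i: one attachment that never happened,
#'   removing the branch block (net of its coupling delta) together with
#'   its entire downstream subtree of caps and blocks.  The parent site is
#'   left as an intact ammonium end group.
#'
#' Adducts (Na+, matrix) are not modelled.
#'
#' @param spec A [dendrimer_spec()].
#' @param missing_caps Number of unreacted peripheral groups (ammonium
#'   form only; must not exceed the peripheral-group count).
#' @param missing_branches Named or indexed integer vector mapping layer
#'   index to the number of missing branch subtrees at that layer.
#' @return A list of class `"defect_variant"` with elements `base`,
#'   `missing_caps`, `missing_branches`, `composition`.
#' @examples
#' sp <- parse_dendrimer_name("G1-6-N")
#' v <- defect_variant(sp, missing_caps = 2)
#' average_mass(sp) - average_mass(v$composition)   # 2 cap masses
#' @export
defect_variant <- function(spec, missing_caps = 0, missing_branches = NULL) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  n_pg <- peripheral_group_count(spec)
  if (missing_caps < 0 || missing_caps != round(missing_caps))
    stop("missing_caps must be a non-negative integer", call. = FALSE)
  if (missing_caps > 0 && spec$terminal_form != "ammonium")
    stop("missing caps are only defined for the ammonium form", call. = FALSE)
  if (missing_caps > n_pg)
    stop("missing_caps (", missing_caps, ") exceeds the ", n_pg,
         " peripheral sites", call. = FALSE)
  n_layers <- length(spec$layers)
  mb <- integer(n_layers)
  if (!is.null(missing_branches)) {
    idx <- if (is.null(names(missing_branches)))
      seq_along(missing_branches) else as.integer(names(missing_branches))
    if (any(idx < 1 | idx > n_layers))
      stop("missing_branches index outside layers 1..", n_layers, call. = FALSE)
    mb[idx] <- as.integer(missing_branches)
    if (any(mb < 0)) stop("missing branch counts must be >= 0", call. = FALSE)
  }
  # available attachment sites at layer i of the perfect structure
  mult <- vapply(spec$layers, `[[`, integer(1), "multiplicity")
  sites <- spec$core$multiplicity * cumprod(c(1, mult))[seq_len(n_layers)]
  if (any(mb > sites))
    stop("missing branches exceed available sites at layer(s) ",
         paste(which(mb > sites), collapse = ", "), call. = FALSE)

  comp <- elemental_composition(spec)
  comp <- comp - missing_caps * spec$cap$composition
  if (any(mb > 0)) {
    acc <- setNames(as.double(comp), names(comp))
    for (i in which(mb > 0)) {
      sub <- branch_subtree_composition(spec, i)
      for (el in names(sub))
        acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) -
          mb[i] * sub[[el]]
    }
    if (any(acc < 0))
      stop("defect pattern removes more atoms than the structure has",
           call. = FALSE)
    comp <- composition(acc)
  }
  structure(list(base = spec, missing_caps = as.integer(missing_caps),
                 missing_branches = mb, composition = comp),
            class = "defect_variant")
}

# Net composition removed when one layer-i attachment (and everything
# grown from it) is absent; the parent end group keeps its cap, so the
# coupling delta (H2O + HCl, whose Cl originates from that parent cap)
# is credited back.  Intermediate counts can be negative for single
# elements, so the bookkeeping runs on signed named vectors and only the
# final result is converted back to a composition.
branch_subtree_composition <- function(spec, layer_index) {
  n_layers <- length(spec$layers)
  signed_add <- function(acc, comp, k = 1) {
    for (el in names(comp))
      acc[el] <- (if (el %in% names(acc)) acc[[el]] else 0) +
        k * unclass(comp)[[el]]
    acc
  }
  contrib <- numeric(0)   # per-site subtree, signed
  for (j in seq(n_layers, layer_index)) {
    block <- spec$layers[[j]]
    term <- numeric(0)
    term <- signed_add(term, block$composition)
    term <- signed_add(term, block$coupling_delta, -1)
    if (j < n_layers) {
      per_site <- signed_add(contrib, spec$cap$composition)
      for (el in names(per_site))
        term[el] <- (if (el %in% names(term)) term[[el]] else 0) +
          block$multiplicity * per_site[[el]]
    } else if (spec$terminal_form == "ammonium") {
      term <- signed_add(term, spec$cap$composition, block$multiplicity)
    }
    contrib <- term
  }
  contrib
}

#' @export
print.defect_variant <- function(x, ...) {
  cat("<defect_variant> of ", dendrimer_name(x$base), ": ",
      x$missing_caps, " missing cap(s)",
      if (any(x$missing_branches > 0))
        paste0(", missing branches at layers [",
               paste(x$missing_branches, collapse = ","), "]") else "",
      "; ", round(average_mass(x$composition), 2), " g/mol\n", sep = "")
  invisible(x)
}

#' Arithmetic mass ladder of missing-cap defects
#'
#' The ladder descends from the perfect mass in steps of one cap mass
#' (113.60 g/mol for cysteamine hydrochloride): species k carries k
#' unreacted end groups.  This is the forward model used to read
#' defectiveness off a mass spectrum.
#'
#' @param spec A [dendrimer_spec()] in ammonium form.
#' @param max_missing_caps Ladder depth; at most the peripheral-group
#'   count.
#' @return A data.frame with columns `missing_caps`, `formula`,
#'   `average_mass`, `monoisotopic_mass`, sorted by descending mass.
#' @examples
#' defect_ladder(parse_dendrimer_name("G1-6-N"), 3)
#' @export
defect_ladder <- function(spec, max_missing_caps) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  n_pg <- peripheral_group_count(spec)
  if (max_missing_caps < 0 || max_missing_caps > n_pg)
    stop("max_missing_caps must lie in 0..", n_pg, call. = FALSE)
  rows <- lapply(0:max_missing_caps, function(k) {
    v <- defect_variant(spec, missing_caps = k)
    data.frame(missing_caps = k,
               formula = format(v$composition),
               average_mass = average_mass(v$composition),
               monoisotopic_mass = monoisotopic_mass(v$composition),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$average_mass), , drop = FALSE]
}
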