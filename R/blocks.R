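#' Define a dendrimer building block
#'
#' A block is a named monomer, core or cap with an elemental composition,
#' a branch multiplicity (how many new reactive end groups one attachment
#' produces) and a coupling delta (the small molecule lost when the block
#' is attached, e.g. water for an amide bond, water plus HCl when coupling
#' onto an ammonium chloride end group).
#'
#' @param name Block name, e.g. `"AB3"`.
#' @param role One of `"core"`, `"branch"`, `"cap"`.
#' @param formula Hill-notation formula string, or a [composition()].
#' @param multiplicity Positive integer: end groups produced per attachment
#'   (4 for the tetravalent core, 3 for AB3, 6 for AB6, 1 for the cap).
#' @param coupling_delta Formula/composition removed on attachment.
#'   Defaults to nothing (the thiol-ene addition of the cap is
#'   atom-economic).
#' @param token Short label used in layer-sequence names; defaults to the
#'   multiplicity for branch blocks.
#' @param smiles SMILES template with `{*}` marking attachment sites
#'   (optional; required only for structure export).
#' @param notes Free-text annotation.
#' @return An object of class `"building_block"`.
#' @examples
#' building_block("AB3", "branch", "C19H26O3Si", 3,
#'                coupling_delta = "H2O.HCl")
#' @export
building_block <- function(name, role = c("branch", "core", "cap"),
                           formula, multiplicity,
                           coupling_delta = NULL, token = NULL,
                           smiles = NULL, notes = "") {
  role <- match.arg(role)
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "composition"))
  if (!is.numeric(multiplicity) || length(multiplicity) != 1L ||
      multiplicity < 1 || multiplicity != round(multiplicity))
    stop("multiplicity must be a positive integer", call. = FALSE)
  if (is.null(coupling_delta))
    coupling_delta <- composition()
  else if (is.character(coupling_delta))
    coupling_delta <- parse_formula(coupling_delta)
  if (is.null(token))
    token <- if (role == "branch") as.character(multiplicity) else name
  structure(list(name = name, role = role, composition = formula,
                 multiplicity = as.integer(multiplicity),
                 coupling_delta = coupling_delta,
                 token = token, smiles = smiles, notes = notes),
            class = "building_block")
}

#' @export
print.building_block <- function(x, ...) {
  cat("<building_block> ", x$name, " [", x$role, "]  ",
      format(x$composition), "  (", round(average_mass(x$composition), 2),
      " g/mol)  multiplicity ", x$multiplicity, "\n", sep = "")
  invisible(x)
}

#' @export
elemental_composition.building_block <- function(x, ...) x$composition

# SMILES fragment templates for the default chemistry.  `{*}` marks an
# attachment site that is filled with an allyl terminus, a cysteamine
# ammonium cap, or the next layer's acyl fragment (see smiles()).
.core_smiles <- "[Si]({*})({*})({*}){*}"
.ab3_smiles <- "C(=O)c1ccc(OCCC[Si]({*})({*}){*})cc1"
.ab6_smiles <- "C(=O)c1cc(OCCC[Si]({*})({*}){*})cc(OCCC[Si]({*})({*}){*})c1"

#' The default building-block registry
#'
#' Ships the poly(amide-carbosilane) chemistry: a tetraallylsilane core
#' (tetravalent, silicon branching centre), the AB3 branch module
#' (para-alkoxybenzoic acid carrying one triallylsilylpropyl wedge,
#' C19H26O3Si, 330 g/mol), the AB6 branch module (3,5-bis-alkoxybenzoic
#' acid carrying two wedges, C31H46O4Si2, 539 g/mol), the cysteamine
#' hydrochloride cap (C2H7NS.HCl), and the benzotriazol-1-yl activated
#' ester of AB3 as a small-molecule reference species.  Branch blocks
#' couple by amide formation onto ammonium chloride end groups, releasing
#' H2O + HCl per bond; the cap adds across a terminal allyl group by
#' radical thiol-ene addition with no leaving group.
#'
#' @return A named list of [building_block()]s with class
#'   `"block_registry"`.
#' @examples
#' reg <- default_registry()
#' round(average_mass(reg$AB3))   # 330
#' round(average_mass(reg$AB6))   # 539
#' @export
default_registry <- function() {
  blocks <- list(
    core = building_block(
      "core", "core", "C12H20Si", 4, token = "core",
      smiles = .core_smiles,
      notes = "tetraallylsilane, tetravalent silicon branching centre"),
    AB3 = building_block(
      "AB3", "branch", "C19H26O3Si", 3,
      coupling_delta = "H2O.HCl", token = "3",
      smiles = .ab3_smiles,
      notes = "para-alkoxybenzoic acid with one triallylsilylpropyl wedge"),
    AB6 = building_block(
      "AB6", "branch", "C31H46O4Si2", 6,
      coupling_delta = "H2O.HCl", token = "6",
      smiles = .ab6_smiles,
      notes = "3,5-bis-alkoxybenzoic acid with two triallylsilylpropyl wedges"),
    CA = building_block(
      "CA", "cap", "C2H7NS.HCl", 1, token = "N",
      notes = "cysteamine hydrochloride; adds across terminal allyls by thiol-ene click"),
    `BtO-AB3` = building_block(
      "BtO-AB3", "branch", "C25H29N3O3Si", 3,
      coupling_delta = "H2O.HCl", token = "3bt",
      notes = "benzotriazol-1-yl activated ester of AB3 (acid OH replaced by OBt)")
  )
  structure(blocks, class = c("block_registry", "list"))
}

#' @export
print.block_registry <- function(x, ...) {
  cat("<block_registry> ", length(x), " blocks\n", sep = "")
  for (b in x) print(b)
  invisible(x)
}

#' Read a building-block registry from a YAML or JSON file
#'
#' The file holds one entry per block with fields `name`, `role`,
#' `formula`, `multiplicity` and optionally `coupling_delta`, `token`,
#' `smiles`, `notes` (Hill-notation formula strings throughout).
#'
#' @param path File path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return A `"block_registry"`.
#' @seealso [write_registry()], [default_registry()]
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else
    yaml::read_yaml(path)
  blocks <- lapply(raw, function(b) {
    required <- c("name", "role", "formula", "multiplicity")
    missing <- setdiff(required, names(b))
    if (length(missing) > 0L)
      stop("registry entry missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    building_block(b$name, b$role, b$formula, b$multiplicity,
                   coupling_delta = b$coupling_delta,
                   token = b$token, smiles = b$smiles,
                   notes = if (is.null(b$notes)) "" else b$notes)
  })
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  structure(blocks, class = c("block_registry", "list"))
}

#' Write a building-block registry to YAML or JSON
#'
#' @param registry A `"block_registry"`.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(unname(registry), function(b) {
    e <- list(name = b$name, role = b$role,
              formula = format(b$composition),
              multiplicity = b$multiplicity)
    if (length(b$coupling_delta) > 0L)
      e$coupling_delta <- format(b$coupling_delta)
    e$token <- b$token
    if (!is.null(b$smiles)) e$smiles <- b$smiles
    if (nzchar(b$notes)) e$notes <- b$notes
    e
  })
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  else
    yaml::write_yaml(entries, path)
  invisible(path)
}

# look a block up, with a clear error naming the registry miss
registry_get <- function(registry, name) {
  if (!name %in% names(registry))
    stop("block '", name, "' not found in registry (have: ",
         paste(names(registry), collapse = ", "), ")", call. = FALSE)
  registry[[name]]
}
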