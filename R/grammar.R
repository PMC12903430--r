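#' Generic: elemental composition of an object
#'
#' @param x A [composition()], [building_block()] or [dendrimer_spec()].
#' @param ... Passed to methods.
#' @return A [composition()].
#' @export
elemental_composition <- function(x, ...) UseMethod("elemental_composition")

#' @export
elemental_composition.composition <- function(x, ...) x

#' Specify a dendrimer as core + ordered layer sequence + terminal form
#'
#' The central object of the construction grammar.  Growth alternates
#' between two reactions: amide coupling of a branch block onto every
#' ammonium end group (losing H2O + HCl per bond) and thiol-ene capping of
#' every terminal allyl with the cap block (atom-economic).  A spec records
#' the core, the branch blocks layer by layer (innermost first) and whether
#' the periphery is left as allyls (`"allyl"`) or capped into ammonium
#' hydrochloride groups (`"ammonium"`).
#'
#' @param layers Character vector of branch-block names, innermost first
#'   (may be empty for the bare core).
#' @param terminal_form `"allyl"` or `"ammonium"`.
#' @param registry A `"block_registry"`; defaults to [default_registry()].
#' @param core Name of the core block in the registry.
#' @param cap Name of the cap block.
#' @return An object of class `"dendrimer_spec"`.
#' @examples
#' sp <- dendrimer_spec(c("AB3", "AB6"), "ammonium")
#' dendrimer_name(sp)            # "G2-3-6-N"
#' peripheral_group_count(sp)    # 72
#' @export
dendrimer_spec <- function(layers = character(0),
                           terminal_form = c("allyl", "ammonium"),
                           registry = default_registry(),
                           core = "core", cap = "CA") {
  terminal_form <- match.arg(terminal_form)
  core_block <- registry_get(registry, core)
  if (core_block$role != "core")
    stop("block '", core, "' does not have role 'core'", call. = FALSE)
  cap_block <- registry_get(registry, cap)
  if (cap_block$role != "cap")
    stop("block '", cap, "' does not have role 'cap'", call. = FALSE)
  layer_blocks <- lapply(layers, function(nm) {
    b <- registry_get(registry, nm)
    if (b$role != "branch")
      stop("layer block '", nm, "' does not have role 'branch'", call. = FALSE)
    b
  })
  structure(list(core = core_block, layers = layer_blocks,
                 terminal_form = terminal_form, cap = cap_block),
            class = "dendrimer_spec")
}

#' @export
print.dendrimer_spec <- function(x, ...) {
  cat("<dendrimer_spec> ", dendrimer_name(x),
      "  generation ", generation(x),
      ", ", peripheral_group_count(x), " peripheral groups, ",
      round(average_mass(x), 1), " g/mol\n", sep = "")
  invisible(x)
}

#' Generation of a dendrimer spec (number of branching layers)
#' @param spec A [dendrimer_spec()].
#' @return Non-negative integer.
#' @export
generation <- function(spec) length(spec$layers)

#' Peripheral-group count
#'
#' The number of end groups on the surface: core valency times the product
#' of the layer branch multiplicities.  This is the branching calculus that
#' gives 108 end groups for the all-AB3 third generation and 864 for the
#' all-AB6 one.
#'
#' @param spec A [dendrimer_spec()].
#' @return Positive integer.
#' @examples
#' peripheral_group_count(dendrimer_spec(c("AB6", "AB6", "AB6")))  # 864
#' @export
peripheral_group_count <- function(spec) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  mult <- vapply(spec$layers, `[[`, integer(1), "multiplicity")
  as.integer(spec$core$multiplicity * prod(mult))
}

#' Canonical name of a dendrimer spec
#'
#' Names follow `G<generation>-<layer tokens, inner to outer>-<A|N>`,
#' e.g. `"G2-6-3-N"` for an AB6 inner layer, AB3 outer layer, ammonium
#' periphery.  [parse_dendrimer_name()] inverts the mapping, so
#' `parse_dendrimer_name(dendrimer_name(spec))` reproduces `spec`.
#'
#' @param spec A [dendrimer_spec()].
#' @return A single string.
#' @export
dendrimer_name <- function(spec) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  tokens <- vapply(spec$layers, `[[`, "", "token")
  suffix <- if (spec$terminal_form == "ammonium") "N" else "A"
  paste(c(paste0("G", generation(spec)), tokens, suffix), collapse = "-")
}

#' @export
format.dendrimer_spec <- function(x, ...) dendrimer_name(x)

#' Parse a dendrimer name back into a spec
#'
#' @param label Name such as `"G2-3-6-N"`.
#' @inheritParams dendrimer_spec
#' @return A [dendrimer_spec()].
#' @seealso [dendrimer_name()]
#' @export
parse_dendrimer_name <- function(label, registry = default_registry(),
                                 core = "core", cap = "CA") {
  stopifnot(is.character(label), length(label) == 1L)
  parts <- strsplit(label, "-", fixed = TRUE)[[1L]]
  if (length(parts) < 2L || !grepl("^G[0-9]+$", parts[1L]))
    stop("malformed dendrimer name '", label,
         "': expected 'G<n>-<layers>-<A|N>' (error at position 1)",
         call. = FALSE)
  gen <- as.integer(sub("^G", "", parts[1L]))
  suffix <- parts[length(parts)]
  if (!suffix %in% c("A", "N"))
    stop("malformed dendrimer name '", label,
         "': terminal form must be 'A' or 'N' (error at position ",
         length(parts), ")", call. = FALSE)
  tokens <- parts[-c(1L, length(parts))]
  if (length(tokens) != gen)
    stop("malformed dendrimer name '", label, "': generation ", gen,
         " but ", length(tokens), " layer token(s) (error at position 2)",
         call. = FALSE)
  branch_names <- names(registry)[vapply(registry, function(b)
    b$role == "branch", logical(1))]
  token_map <- setNames(branch_names,
                        vapply(registry[branch_names], `[[`, "", "token"))
  layers <- character(length(tokens))
  for (i in seq_along(tokens)) {
    if (!tokens[i] %in% names(token_map))
      stop("malformed dendrimer name '", label, "': unknown layer token '",
           tokens[i], "' (error at position ", i + 1L, ")", call. = FALSE)
    layers[i] <- token_map[[tokens[i]]]
  }
  dendrimer_spec(layers,
                 terminal_form = if (suffix == "N") "ammonium" else "allyl",
                 registry = registry, core = core, cap = cap)
}

#' Enumerate all layer sequences of a given generation
#'
#' With k interchangeable branch blocks there are k^n distinct ordered
#' layer sequences in generation n; with the shipped AB3/AB6 pair this is
#' the 2^n combinatorial family (8 compounds in generation 3, 14 across
#' generations 1-3).  Order is deterministic: lexicographic by layer-name
#' tuple.
#'
#' @param generation Positive integer.
#' @param blocks Character vector of branch-block names; default both
#'   shipped modules.
#' @inheritParams dendrimer_spec
#' @return List of [dendrimer_spec()]s of length `length(blocks)^generation`.
#' @examples
#' length(enumerate_sequences(3))   # 8
#' @export
enumerate_sequences <- function(generation, blocks = c("AB3", "AB6"),
                                terminal_form = c("allyl", "ammonium"),
                                registry = default_registry(),
                                core = "core", cap = "CA") {
  terminal_form <- match.arg(terminal_form)
  if (!is.numeric(generation) || length(generation) != 1L ||
      generation < 1 || generation != round(generation))
    stop("generation must be a positive integer", call. = FALSE)
  if (length(blocks) == 0L)
    stop("blocks must be non-empty", call. = FALSE)
  blocks <- sort(unique(blocks))
  grids <- rep(list(blocks), generation)
  # expand.grid varies the first factor fastest; build so the resulting
  # rows sort lexicographically by (layer1, layer2, ...)
  g <- expand.grid(rev(grids), stringsAsFactors = FALSE)
  g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
  lapply(seq_len(nrow(g)), function(i)
    dendrimer_spec(as.character(unlist(g[i, ])), terminal_form = terminal_form,
                   registry = registry, core = core, cap = cap))
}

#' Histogram of peripheral-group counts over all sequences of a generation
#'
#' For two blocks the class multiplicities follow the binomial
#' coefficients of Pascal's triangle: in generation 3 one structure each
#' with 108 and 864 end groups and three each with 216 and 432 (1:3:3:1).
#'
#' @inheritParams enumerate_sequences
#' @return Named integer vector: `histogram["216"]` is the number of
#'   sequences with 216 peripheral groups; names sorted numerically.
#' @examples
#' pg_class_histogram(3)   # 108:1 216:3 432:3 864:1
#' @export
pg_class_histogram <- function(generation, blocks = c("AB3", "AB6"),
                               registry = default_registry(),
                               core = "core", cap = "CA") {
  specs <- enumerate_sequences(generation, blocks, registry = registry,
                               core = core, cap = cap)
  counts <- vapply(specs, peripheral_group_count, integer(1))
  tab <- table(counts)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(as.numeric(names(out)))]
}

#' Elemental composition of a dendrimer spec
#'
#' Assembled by the growth recursion: start from the core, and for each
#' layer cap every end group (thiol-ene addition of the cap, no atoms
#' lost) and couple the branch block onto every resulting ammonium group
#' (losing the block's coupling delta per bond).  The ammonium form adds
#' one cap per peripheral group on top of the allyl form, so
#' `mass(N form) - mass(A form) = N_PG * mass(cap)` identically.
#'
#' @param x A [dendrimer_spec()].
#' @param ... Unused.
#' @return A [composition()].
#' @examples
#' sp <- parse_dendrimer_name("G2-3-6-N")
#' round(average_mass(sp))   # 17106
#' @export
elemental_composition.dendrimer_spec <- function(x, ...) {
  comp <- x$core$composition
  n_sites <- as.integer(x$core$multiplicity)
  for (block in x$layers) {
    # cap the current periphery, then amide-couple the next layer on
    comp <- comp + n_sites * x$cap$composition
    comp <- comp + n_sites * block$composition - n_sites * block$coupling_delta
    n_sites <- n_sites * block$multiplicity
  }
  if (x$terminal_form == "ammonium")
    comp <- comp + n_sites * x$cap$composition
  comp
}

#' @export
elemental_composition.default <- function(x, ...)
  stop("no elemental_composition method for class ",
       paste(class(x), collapse = "/"), call. = FALSE)

#' Summary table for a set of dendrimer specs
#'
#' @param specs A [dendrimer_spec()] or list of them.
#' @return A data.frame with name, generation, layer sequence, peripheral
#'   group count, formula, average and monoisotopic mass (g/mol).
#' @export
dendrimer_table <- function(specs) {
  if (inherits(specs, "dendrimer_spec")) specs <- list(specs)
  rows <- lapply(specs, function(sp) {
    comp <- elemental_composition(sp)
    data.frame(
      name = dendrimer_name(sp),
      generation = generation(sp),
      layers = paste(vapply(sp$layers, `[[`, "", "name"), collapse = ","),
      n_pg = peripheral_group_count(sp),
      formula = format(comp),
      average_mass = round(average_mass(comp), 2),
      monoisotopic_mass = round(monoisotopic_mass(comp), 4),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
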