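# SMILES assembly for the shipped chemistry.
#
# Each block carries a template in which "{*}" marks an attachment site.
# A site is filled with one of three terminations:
#   allyl periphery      "CC=C"
#   ammonium cap         "CCCSCC[NH3+]"  (+ one [Cl-] counter-ion,
#                        appended at top level because dots are illegal
#                        inside branches)
#   next layer           "CCCSCCN" + the layer block's acyl template
# The three-carbon linker is the former allyl after anti-Markovnikov
# thiol addition.

.site_allyl <- "CC=C"
.site_cap <- "CCCSCC[NH3+]"
.site_link <- "CCCSCCN"

split_sites <- function(template) {
  # sentinel keeps a trailing "{*}" from being dropped by strsplit
  parts <- strsplit(paste0(template, "\003"), "{*}", fixed = TRUE)[[1L]]
  parts[length(parts)] <- sub("\003$", "", parts[length(parts)])
  parts
}

fill_sites <- function(template, fillers) {
  parts <- split_sites(template)
  n_sites <- length(parts) - 1L
  if (n_sites != length(fillers))
    stop("template has ", n_sites, " sites but ", length(fillers),
         " fillers were supplied", call. = FALSE)
  out <- parts[1L]
  for (i in seq_len(n_sites)) out <- paste0(out, fillers[i], parts[i + 1L])
  out
}

count_sites <- function(template) length(split_sites(template)) - 1L

#' SMILES encoding of a dendrimer spec
#'
#' Recursively assembles a single-line SMILES string from the attachment
#' templates carried by the registry blocks.  Ammonium peripheries are
#' written as `[NH3+]` groups with the matching number of `[Cl-]`
#' counter-ions appended as separate components, so the encoded atom
#' counts equal [elemental_composition()] exactly (hydrogens included).
#' Ring-closure digits are assigned uniquely across the whole molecule
#' using `%nn` notation where needed.
#'
#' @param spec A [dendrimer_spec()] whose blocks all carry `smiles`
#'   templates.
#' @return A single SMILES string.
#' @examples
#' smiles(dendrimer_spec())   # tetraallylsilane
#' @export
smiles <- function(spec) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  for (b in c(list(spec$core), spec$layers)) {
    if (is.null(b$smiles))
      stop("block '", b$name, "' carries no SMILES template; ",
           "structure export is unsupported for it", call. = FALSE)
  }
  build <- function(level) {
    # returns the filler string for one attachment site entering `level`
    if (level > length(spec$layers)) {
      if (spec$terminal_form == "ammonium") return(.site_cap)
      return(.site_allyl)
    }
    block <- spec$layers[[level]]
    tpl <- renumber_rings(block$smiles, level)
    n_sites <- count_sites(tpl)
    fillers <- vapply(seq_len(n_sites), function(i) build(level + 1L), "")
    paste0(.site_link, fill_sites(tpl, fillers))
  }

  core_tpl <- renumber_rings(spec$core$smiles, 0L)
  n_core <- count_sites(core_tpl)
  fillers <- vapply(seq_len(n_core), function(i) build(1L), "")
  body <- fill_sites(core_tpl, fillers)
  n_cl <- if (spec$terminal_form == "ammonium")
    peripheral_group_count(spec) else 0L
  paste(c(body, rep("[Cl-]", n_cl)), collapse = ".")
}

# Rewrite a template's ring labels by nesting depth.  A template's ring
# stays open only across its own nested fillers, so sibling copies may
# reuse the same digit once their ring has closed; only ancestors at
# different depths must differ.  Two ring labels per template and up to
# four nesting levels fit comfortably in the nine single-digit labels.
renumber_rings <- function(template, level) {
  digits <- unique(regmatches(template,
                              gregexpr("(?<![%0-9])[0-9]", template,
                                       perl = TRUE))[[1L]])
  if (length(digits) > 2L)
    stop("block templates may use at most two ring labels", call. = FALSE)
  # two-pass replacement via placeholders so a new label never collides
  # with a yet-unprocessed original digit
  for (j in seq_along(digits))
    template <- gsub(paste0("(?<![%0-9])", digits[j]),
                     paste0("\001", j, "\002"), template, perl = TRUE)
  for (j in seq_along(digits)) {
    label <- as.character((level * 2L + j - 1L) %% 9L + 1L)
    template <- gsub(paste0("\001", j, "\002"), label, template, fixed = TRUE)
  }
  template
}

#' Count atoms in a SMILES string
#'
#' A minimal reader for the restricted SMILES dialect this package emits
#' (organic-subset C/N/O/S, aromatic `c`, bracket atoms with explicit
#' hydrogens and charges, `=` bonds, branches, `%nn` ring closures, dot
#' components).  Implicit hydrogens are filled to standard valences
#' (C 4, N 3, O 2, S 2); an aromatic carbon is treated as contributing
#' one bond more than its written connections.  Used to audit that an
#' emitted structure matches its elemental composition atom for atom.
#'
#' @param x A SMILES string.
#' @return A [composition()] including hydrogens.
#' @examples
#' smiles_atom_counts("C(=C)C[Si](CC=C)(CC=C)CC=C")
#' @export
smiles_atom_counts <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  valence <- c(C = 4, N = 3, O = 2, S = 2)
  counts <- numeric(0)
  h_total <- 0
  atoms_order <- numeric(0)  # per-atom bond-order sum
  atoms_sym <- character(0)
  atoms_arom <- logical(0)
  atoms_bracket <- logical(0)
  chars <- strsplit(x, "")[[1L]]
  i <- 1L
  n <- length(chars)
  prev_stack <- integer(0)   # open-branch return points
  prev_atom <- NA_integer_
  pend_bond <- 1             # bond order to use for next connection
  rings <- list()            # label -> c(atom, order)

  connect <- function(a, b, order) {
    atoms_order[a] <<- atoms_order[a] + order
    atoms_order[b] <<- atoms_order[b] + order
  }
  add_atom <- function(sym, arom, bracket, h_explicit = NA) {
    atoms_sym[length(atoms_sym) + 1L] <<- sym
    atoms_arom[length(atoms_arom) + 1L] <<- arom
    atoms_bracket[length(atoms_bracket) + 1L] <<- bracket
    atoms_order[length(atoms_order) + 1L] <<- 0
    id <- length(atoms_sym)
    if (!is.na(prev_atom)) connect(prev_atom, id, pend_bond)
    prev_atom <<- id
    pend_bond <<- 1
    if (!is.na(h_explicit)) h_total <<- h_total + h_explicit
    id
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- regmatches(body, regexpr("^[A-Z][a-z]?", body))
      rest <- sub("^[A-Z][a-z]?", "", body)
      hmatch <- regmatches(rest, regexpr("H[0-9]*", rest))
      hn <- if (length(hmatch) == 0L) 0
            else if (hmatch == "H") 1
            else as.numeric(sub("H", "", hmatch))
      add_atom(sym, arom = FALSE, bracket = TRUE, h_explicit = hn)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "S")) {
      # two-letter organic-subset symbols (Cl, Br) never occur unbracketed
      # in the emitted dialect
      add_atom(ch, arom = FALSE, bracket = FALSE)
      i <- i + 1L
    } else if (ch == "c") {
      add_atom("C", arom = TRUE, bracket = FALSE)
      i <- i + 1L
    } else if (ch == "=") {
      pend_bond <- 2; i <- i + 1L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev_atom); i <- i + 1L
    } else if (ch == ")") {
      prev_atom <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev_atom <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { label <- paste(chars[(i + 1L):(i + 2L)], collapse = ""); i <- i + 3L }
      else { label <- ch; i <- i + 1L }
      if (is.null(rings[[label]])) {
        rings[[label]] <- c(prev_atom, pend_bond)
      } else {
        connect(rings[[label]][1L], prev_atom, max(pend_bond, rings[[label]][2L]))
        rings[[label]] <- NULL
      }
      pend_bond <- 1
    } else {
      stop("unsupported SMILES character '", ch, "' at position ", i,
           call. = FALSE)
    }
  }
  if (length(rings) > 0L)
    stop("unclosed ring bond(s) in SMILES", call. = FALSE)

  for (k in seq_along(atoms_sym)) {
    sym <- atoms_sym[k]
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + 1
    if (!atoms_bracket[k]) {
      v <- valence[[sym]]
      used <- atoms_order[k] + if (atoms_arom[k]) 1 else 0
      h_total <- h_total + max(0, v - used)
    }
  }
  if (h_total > 0)
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0) + h_total
  composition(counts)
}
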