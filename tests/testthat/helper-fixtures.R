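# shared fixtures: all fourteen layer sequences of generations 1-3, and a
# brute-force atom-bookkeeping oracle for dendrimer compositions that
# tracks every reaction event explicitly (independent of the package's
# growth recursion)

all_14_names <- function(form = "N") {
  unlist(lapply(1:3, function(g) {
    grid <- expand.grid(rep(list(c("3", "6")), g), stringsAsFactors = FALSE)
    apply(grid, 1, function(tok) paste(c(paste0("G", g), tok, form),
                                       collapse = "-"))
  }))
}

# independent composition oracle: simulate the synthesis event by event,
# keeping a running count of every atom added or removed
brute_force_composition <- function(layer_tokens, form) {
  wt <- list(
    core = c(C = 12, H = 20, Si = 1),
    cap = c(C = 2, H = 8, Cl = 1, N = 1, S = 1),
    `3` = c(C = 19, H = 26, O = 3, Si = 1),
    `6` = c(C = 31, H = 46, O = 4, Si = 2),
    h2o_hcl = c(H = 3, O = 1, Cl = 1))
  add <- function(acc, v, times = 1) {
    for (el in names(v)) acc[el] <- (if (is.na(acc[el])) 0 else acc[el]) + v[[el]] * times
    acc
  }
  mult <- c(`3` = 3, `6` = 6)
  acc <- add(c(C = 0), wt$core)
  sites <- 4
  for (tok in layer_tokens) {
    acc <- add(acc, wt$cap, sites)          # cap every allyl
    acc <- add(acc, wt[[tok]], sites)       # couple the next block
    acc <- add(acc, -wt$h2o_hcl, sites)     # amide bond loses H2O + HCl
    sites <- sites * mult[[tok]]
  }
  if (form == "N") acc <- add(acc, wt$cap, sites)
  acc[!is.na(acc) & acc != 0]
}

expect_composition_equal <- function(comp, counts) {
  counts <- counts[sort(names(counts))]
  got <- unclass(comp)[sort(names(comp))]
  expect_equal(got, as.double(counts)[order(names(counts))],
               ignore_attr = TRUE)
  expect_identical(sort(names(comp)), sort(names(counts)))
}
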