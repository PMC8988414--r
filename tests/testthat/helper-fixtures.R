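# Fixtures built in code: tiny hand-checkable trees plus a random-tree
# generator used for the reduction-vs-nodal oracle sweeps.

seg_row <- function(id, parent, artery, l, r, sten = FALSE, site = FALSE,
                    dist = NA_real_) {
  data.frame(segment_id = id, parent_id = parent, artery = artery,
             length_cm = l, mean_radius_cm = r, has_stenosis = sten,
             is_measurement_site = site, site_distance_cm = dist,
             stringsAsFactors = FALSE)
}

# single LAD segment carrying a measurement site at its distal end
single_segment_tree <- function(l = 10, r = 0.15) {
  coronary_tree(seg_row("LAD1", NA_character_, "LAD", l, r, site = TRUE, dist = l))
}

# LAD root splitting into two children (one a site), used for hand algebra
bifurcation_tree <- function() {
  coronary_tree(rbind(
    seg_row("LAD1", NA_character_, "LAD", 4, 0.2),
    seg_row("LAD2a", "LAD1", "LAD", 3, 0.15, site = TRUE, dist = 7),
    seg_row("LAD2b", "LAD1", "LAD", 5, 0.12)
  ))
}

# 9 segments over three arteries (LAD 4 / LCX 3 / RCA 2), sites on LAD+LCX
example_tree_df <- function() {
  rbind(
    seg_row("LAD_prox", NA_character_, "LAD", 3.5, 0.2),
    seg_row("LAD_sten", "LAD_prox", "LAD", 1.5, 0.06, sten = TRUE),
    seg_row("LAD_site", "LAD_sten", "LAD", 1.2, 0.19, site = TRUE, dist = 6.2),
    seg_row("LAD_d1", "LAD_site", "LAD", 6, 0.15),
    seg_row("LCX_prox", NA_character_, "LCX", 3, 0.17),
    seg_row("LCX_sten", "LCX_prox", "LCX", 1.8, 0.07, sten = TRUE),
    seg_row("LCX_site", "LCX_sten", "LCX", 1.4, 0.165, site = TRUE, dist = 6.2),
    seg_row("RCA_prox", NA_character_, "RCA", 4, 0.21),
    seg_row("RCA_d1", "RCA_prox", "RCA", 7, 0.16)
  )
}

example_tree <- function() coronary_tree(example_tree_df())

# random three-artery forest with n segments total; random attachment within
# each artery, radii/lengths spanning healthy-to-stenotic calibres
random_tree <- function(n = 20) {
  stopifnot(n >= 3)
  counts <- c(1L, 1L, 1L) + stats::rmultinom(1, n - 3L, rep(1 / 3, 3))[, 1]
  rows <- list()
  for (k in seq_along(ARTERY <- c("LAD", "LCX", "RCA"))) {
    a <- ARTERY[k]
    for (i in seq_len(counts[k])) {
      id <- sprintf("%s_%02d", a, i)
      parent <- if (i == 1L) NA_character_ else sprintf("%s_%02d", a, sample.int(i - 1L, 1L))
      rows[[length(rows) + 1L]] <- seg_row(
        id, parent, a,
        l = stats::runif(1, 0.5, 8),
        r = stats::runif(1, 0.05, 0.25)
      )
    }
  }
  coronary_tree(do.call(rbind, rows))
}

default_setup <- function() {
  list(params = hemo_params(), chamber = chamber_params(),
       states = default_activity_states())
}

tree_csv_text <- function(df) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  c(
    "segment_id,parent_id,artery,length_cm,mean_radius_cm,has_stenosis,is_measurement_site,site_distance_cm",
    paste(df$segment_id, ifelse(is.na(df$parent_id), "", df$parent_id), df$artery,
          fmt(df$length_cm), fmt(df$mean_radius_cm),
          tolower(df$has_stenosis), tolower(df$is_measurement_site),
          fmt(df$site_distance_cm), sep = ",")
  )
}
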