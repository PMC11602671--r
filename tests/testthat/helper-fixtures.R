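# Small deterministic fixtures built in code.

# Trait table with hand-picked categories for closed-form checks.
toy_traits <- function() {
  data.frame(
    species = c("spA", "spB", "spC"),
    max_length = c("0-7", ">80", "0-7"),
    mobility = c("sedentary", "highly_mobile", "sedentary"),
    activity = c("day", "night", "day"),
    gregariousness = c("solitary", "large_schools", "solitary"),
    position = c("benthic", "pelagic", "benthic"),
    diet = c("herbivore_detritivore", "piscivore", "herbivore_detritivore"),
    stringsAsFactors = FALSE
  )
}

# Six-rank taxonomy with controllable sharing depth.
toy_taxonomy <- function() {
  data.frame(
    species = c("sp1", "sp2", "sp3", "sp4"),
    genus = c("g1", "g1", "g2", "g3"),
    family = c("f1", "f1", "f1", "f2"),
    order = c("o1", "o1", "o1", "o2"),
    subclass = c("sc1", "sc1", "sc1", "sc2"),
    class = c("c1", "c1", "c1", "c2"),
    superclass = c("SC", "SC", "SC", "SC"),
    stringsAsFactors = FALSE
  )
}

# Survey records for a deterministic 2-stratum community with a known
# presence pattern: n_shared + n_shallow + n_deep species.
venn_records <- function(n_shared, n_shallow, n_deep) {
  sp_shared <- sprintf("sh%03d", seq_len(n_shared))
  sp_shal <- sprintf("sa%03d", seq_len(n_shallow))
  sp_deep <- sprintf("dp%03d", seq_len(n_deep))
  mk <- function(tid, depth, species) {
    data.frame(transect_id = tid, site = "A", depth = depth, season = "cold",
               year = "2021", species = species, count = 1L,
               quality_flag = "ok", stringsAsFactors = FALSE)
  }
  rbind(mk("t1", 10, c(sp_shared, sp_shal)),
        mk("t2", 40, c(sp_shared, sp_deep)))
}
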