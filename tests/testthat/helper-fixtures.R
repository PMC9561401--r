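# Shared fixtures and independent oracles.

# Published discriminator tables (regression fixture): 2x2 cell counts per
# rule (a = exposed high, b = exposed low, c/d complements of group sizes
# 6 and 23), the reported adjusted odds ratio, reported true-positive rate
# (%) and reported importance label ("" = not significant). One row is a
# suspected erratum in the source (its printed OR is not reproducible from
# its printed counts by the adjustment formula) and is flagged `anomaly`.
published_rules <- function() {
  txt <- "name,a,b,or,importance,anomaly
homeplace_pop,5,6,6.07,high,FALSE
school_sport,4,1,14.67,high,FALSE
height_diff_t1t2,4,2,9.33,high,FALSE
tibia_length_t1,2,0,9.2,moderate,FALSE
arm_height_ratio_t1,6,7,12,high,FALSE
torso_diff_t1t2,3,1,8.25,moderate,FALSE
tibia_diff_t1t2,5,6,6.07,high,FALSE
arm_ratio_diff_t1t2,2,0,9.2,moderate,FALSE
duncan_pp_t1,5,6,6.07,high,FALSE
broad_jump_t1,4,4,5.07,high,FALSE
sayers_pp_t2,5,6,6.07,high,FALSE
duncan_pp_t2,5,6,6.07,high,FALSE
cmj_height_t2,5,6,6.07,high,FALSE
squat_jump_t2,2,0,9.2,moderate,FALSE
back_squat_t1,3,1,8.25,moderate,FALSE
front_squat_t1,6,8,10,high,FALSE
back_squat_t2,2,0,9.2,moderate,FALSE
front_squat_t2,3,2,5.25,moderate,FALSE
back_squat_diff_t1t2,0,12,0,low,FALSE
ohs_torso_t1,2,0,9.2,moderate,FALSE
mastery_approach,3,1,8.25,moderate,FALSE
mastery_avoidance,2,21,0.04,high,FALSE
performance_approach,4,4,5.07,high,FALSE
commitment_training,6,10,7.09,high,FALSE
total_preparation,3,6,1.82,,FALSE
relative_importance,6,10,7.09,high,FALSE
harmonious_passion,5,2,17.5,high,FALSE
obsessive_passion,5,4,9.5,high,FALSE
conscientiousness,5,5,7.5,high,FALSE
openness,2,0,9.2,moderate,FALSE
extraversion,6,9,8.4,high,FALSE
doubts_about_actions,0,22,0,high,FALSE
organization,5,2,17.5,high,FALSE
flex_age10,2,0,9.2,moderate,FALSE
flex_age11,2,0,9.2,moderate,FALSE
flex_age12,2,0,9.2,moderate,FALSE
flex_age13,2,0,9.2,moderate,FALSE
flex_age14,4,0,30.67,high,FALSE
flex_age15,3,0,17.25,high,FALSE
sc_age9,2,0,9.2,moderate,FALSE
sc_age10,2,0,9.2,moderate,FALSE
sc_age15,3,1,8.25,moderate,FALSE
combined_age13,2,17,0.06,low,TRUE
combined_age15,5,3,12.5,high,FALSE
cum_flex_t1,3,0,17.25,high,FALSE
cum_sc_t1,3,0,17.25,high,FALSE
cum_wl_t1,5,4,9.5,high,FALSE
cum_comp_t1,6,8,10,high,FALSE
cum_comptime_t1,5,4,9.5,high,FALSE
cum_flex_t2,4,1,14.67,high,FALSE
cum_sc_t2,3,1,8.25,high,FALSE
cum_wl_t2,4,2,9.33,high,FALSE
cum_comp_t2,6,8,10,high,FALSE
cum_comptime_t2,5,3,12.5,high,FALSE
cum_flex_t1t2,6,5,18,high,FALSE
cum_wl_t1t2,3,2,5.25,high,FALSE"
  d <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  d$c <- 6L - d$a
  d$d <- 23L - d$b
  d$tpr <- d$a / 6
  d$importance[is.na(d$importance)] <- ""
  d
}

# Independent Fisher oracle: full enumeration over all 2x2 tables with the
# observed fixed margins, probabilities from binomial coefficients.
enum_fisher <- function(a, b, c, d,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n_high <- a + c; n_low <- b + d; m <- a + b; n <- n_high + n_low
  as <- max(0, m - n_low):min(m, n_high)
  pr <- choose(n_high, as) * choose(n_low, m - as) / choose(n, m)
  obs <- pr[match(a, as)]
  switch(alternative,
         two.sided = sum(pr[pr <= obs * (1 + 1e-7)]),
         greater = sum(pr[as >= a]),
         less = sum(pr[as <= a]))
}

# standard two-group label vector (23 low + 6 high, the study design)
study_labels <- function(n_low = 23, n_high = 6) {
  rep(c("low", "high"), c(n_low, n_high))
}

# small synthetic cohort for fast unit tests
tiny_cohort <- function(seed = 5, n_attributes = 40, planted = list()) {
  generate_cohort(cohort_config(n_attributes = n_attributes, seed = seed,
                                planted_effects = planted))
}
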