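# soundenrich

Sound-enrichment therapy for tinnitus works on the premise that tinnitus
linked to cochlear hearing loss reflects maladaptive central gain: reduced
input from the damaged frequency region drives up spontaneous activity in
the central auditory pathway. Re-supplying acoustic energy in exactly that
region — rather than generic broadband masking — aims at the mechanism
itself. `soundenrich` is an R toolkit for running such a protocol: it
screens candidates whose tinnitus is plausibly hearing-loss driven,
synthesizes each patient's individualized therapy sound from their
audiogram, verifies the stimulus spectra, and lays out the phased listening
schedule.

## What it computes

**Eligibility.** A patient qualifies when the hearing threshold at the
matched tinnitus pitch `f_t` lies in the 45–55 dB HL window — per the
discordant damage model the loss depth at which outer-hair-cell damage
maximally exceeds inner-hair-cell damage — with positive residual
inhibition (tinnitus suppressed after 60 s of narrowband noise at
MML + 10 dB), tonal chronic (> 6 months) tinnitus, no threshold above
90 dB HL, and no organic cause. Whole cohorts are screened with exclusions
tallied under one primary reason each.

**Study stimulus (v3).** Seeded Gaussian white noise at 44.1 kHz is shaped
in the frequency domain by two envelopes and mixed in mono:

- *v1* — band-pass over the hearing-loss region `[f_start, f_end]`
  (thresholds above 15 dB HL), with in-band gain `G(f) ∝ θ(f) − 15` dB
  (more loss → more energy) normalized to a 0 dB maximum. Band edges are
  raised-cosine transitions of width `w = clamp(10/Δ, 0.05, 1)` octaves,
  where `Δ` is the threshold step at the loss onset: an abrupt onset gets
  a sharp edge, a shallow one a smooth edge.
- *v2* — a flat band exactly `[0.9 f_t, 1.1 f_t]`, mixed +6 dB above v1's
  plateau so the combined spectrum peaks at the tinnitus pitch.

**Placebo stimulus.** The same carrier confined to the normal-hearing
range `[f_min, f_start]` with minimal smoothing, so no energy reaches the
loss region.

**Dosing.** Three de-escalating phases: months 0–1 at 6 h/day above the
tinnitus loudness level (TLL), months 1–3 at 3 h/day just above the
suppression (minimum masking) level, months 3–6 at 2 h/day just below the
TLL; "just" is one 5 dB audiometric step.

Every synthesized signal can be verified with a Welch averaged-periodogram
report (peak frequency, −3 dB band edges, out-of-band rejection).

## Worked example

```r
library(soundenrich)

a <- read_audiogram(system.file("extdata", "synthetic_example_audiogram.csv",
                                package = "soundenrich"))
p <- read_profile(system.file("extdata", "synthetic_example_profile.json",
                              package = "soundenrich"))

check_eligibility(p, a)
#> <eligibility_result> eligible

loss_region(a)
#> <hearing_loss_region> 1000-8000 Hz; onset 20 dB HL (adjacent normal 10 dB HL @ 500 Hz)
```

The loss spans 1–8 kHz; the onset step is `|20 − 10| = 10` dB, so the
band edges get `clamp(10/10, 0.05, 1) = 1` octave of smoothing. The
patient's pitch is 4 kHz (threshold 50 dB HL), so the emphasis band is
3600–4400 Hz:

```r
cfg <- synthesis_config(duration_s = 4, seed = 42)
v3 <- synthesize_study(a, p, cfg)
spectrum_report(v3, passband_hint = c(1000, 8000))
#> <spectrum_report> peak 3946 Hz; -3 dB edges 3585-9830 Hz; out-of-band rejection 43 dB

placebo <- synthesize_placebo(a, cfg)
placebo$meta$passband
#> [1]  125 1000

write_wav(v3, "study.wav")   # mono 16-bit PCM, 44100 Hz
```

The spectrum peaks inside the 3.6–4.4 kHz emphasis band, the placebo fills
only the normal 125–1000 Hz range, and out-of-band energy sits > 40 dB
below the passband. The schedule for this patient (TLL 60, MML 50 dB HL):

```r
build_plan(p)
#> # A tibble: 3 x 6
#>   phase start_month end_month daily_hours level_rule                 level_anchor_db_hl
#>   <int>       <dbl>     <dbl>       <dbl> <chr>                                   <dbl>
#> 1     1           0         1           6 ABOVE_TINNITUS_COMFORTABLE                 65
#> 2     2           1         3           3 JUST_ABOVE_SUPPRESSION                     55
#> 3     3           3         6           2 JUST_BELOW_TINNITUS                        55
```

Screening a synthetic 127-record cohort built with the four exclusion
categories (6 organic, 11 pitch-threshold-out, 10 RI-negative, 4 profound):

```r
flow <- filter_cohort(gen_cohort(fixture_spec(seed = 2)))
glance(flow)
#> # A tibble: 1 x 3
#>   admitted excluded included
#>      <int>    <int>    <int>
#> 1      127       31       96

randomize(sprintf("S%03d", 1:96), seed = 2, ratio = 52/96) |> dplyr::count(group)
#> # A tibble: 2 x 2
#>   group       n
#>   <chr>   <int>
#> 1 placebo    44
#> 2 study      52
```

A thin command-line wrapper over the same functions lives in
`inst/cli/soundenrich.R` (subcommands `screen`, `synth`, `verify`, `plan`,
`fixtures`).

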