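# damtel

Acoustic-telemetry processing for dam-scale studies of juvenile fish:
coded-transmission validation, false-positive filtering,
time-difference-of-arrival (TDOA) 3-D localization, trajectory cleaning,
passage-route assignment, and GPS-referenced accuracy validation — plus a
seeded simulator that makes the whole chain testable without field data.

## The scientific problem

Juvenile salmonids carrying JSATS-style acoustic transmitters are tracked
through hydropower dams by arrays of cabled hydrophones on the dam face.
Each transmission is a 31-bit message (7-bit sync, 16-bit tag id, 8-bit
CRC); receivers also decode noise, reflections and corrupted messages, so
raw decode streams must be filtered before analysis. Surviving
multi-receiver messages are localized by hyperbolic TDOA: with receiver
positions $h_i$, sound speed $c$ and the earliest arrival as reference,
the tag position $p$ minimizes

$$\sum_i \left( \Delta t_i - \frac{\lVert p-h_i\rVert -
\lVert p-h_{\mathrm{ref}}\rVert}{c} \right)^2 .$$

Cleaned 3-D tracks then yield each fish's passage route through the dam
(powerhouse turbine or juvenile bypass; regular spillbay or surface
weir), cross-checked by a second, track-free method based on which piers
heard the last transmission. Accuracy is validated against a
GPS-referenced tag towed on survey transects.

## Worked example

Tag-code layer — encode, validate, and measure the false-validation rate
of random words (the CRC leaves 1 word in 256 looking valid):

```r
library(damtel)
cw <- encode_tag(1234L)
codeword_to_string(cw)
#> "1110010000001001101001001100100"
validate_decode(cw)$valid
#> TRUE
set.seed(1)
1 / mean(validate_words(floor(runif(1e5) * 2^31)))
#> 258.3979
```

End-to-end pipeline on simulated fish (14-pier dam-face array, three
tagged fish, 10-minute records):

```r
cfg <- default_config(seed = 42L)
cfg$fish$n_tags <- 3L
cfg$fish$duration <- 600
res <- run_pipeline(cfg, out_dir = tempdir(),
                    stages = c("simulate", "filter", "track", "route"))
res$log
#>                     stage  n_in n_out
#> 1                simulate     0 14508
#> 2        multipath_filter 14508 12159
#> 3          group_messages 12159   747
#> 4 single_detection_filter   747   429
#> 5      message_pri_filter   429   429
#> 6                   track   429   416
#> 7                   route     3     3
res$routes[, c("tag_id", "route", "subroute", "hole", "review")]
#>   tag_id      route subroute hole review
#> 1   9825 powerhouse  turbine  T04  FALSE
#> 2  55424 powerhouse  turbine  T01  FALSE
#> 3  35019 powerhouse  turbine  T03  FALSE
```

All three assigned holes match the bays the simulated fish actually
passed through. GPS-referenced survey validation (10 µs timing noise,
0.28 m/s transects, 3 s PRI) reproduces the qualitative field pattern —
centimeter-scale horizontal medians with depth error growing with range:

```r
val <- run_survey_validation(cfg, make_pier_array(14), 
                             propagation_model(c_sound = sound_speed(15),
                                               sigma_t = 1e-5))
val$table[c(1, 5, 10, 15), c("distance", "median_dx", "median_dy", "rms_dz")]
#>    distance median_dx median_dy rms_dz
#> 1        10    0.0483    0.0028 0.0246
#> 5        50    0.0189    0.0037 0.0738
#> 10      100    0.0203    0.0057 0.1170
#> 15      150    0.0267    0.0088 0.1521
```

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","damtel",package="damtel"))')" \
  all --config config.yaml --out-dir out/
```

Subcommands `simulate | filter | localize | track | route | validate |
all`; outputs are CSVs in the deposited-data schemas (`schema()` lists
them) plus a per-stage count log.

## Documentation

See the methods vignette (`vignettes/damtel-methods.Rmd`) for the model,
parameter defaults and rationale, numerical choices, simulator scope,
and limitations.
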