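{
  "seed": 1,
  "breed": "Guzao",
  "model": "et",
  "simulate": { "n_batches": 2, "n_days": 40, "breeds": ["Guzao"] },
  "preprocess": { "weighing_hour": "08:00", "interval_min_len": 5,
                  "interval_max_len": 35, "interval_stride": 3 },
  "schedule": { "start_weight": 340, "target_weight": 770,
                "start_day": 20, "target_day": 39,
                "tolerance": 10, "max_iter": 20,
                "daily_min": 5, "daily_max": 250, "max_rel_change": 0.10 },
  "economics": { "adlib_intake_g": 3000, "adlib_gain_g": 800,
                 "feed_price": 14, "n_birds_commercial": 1000 }
}
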