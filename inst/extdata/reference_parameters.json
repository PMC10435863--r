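{
  "arms": {
    "PP1M": {
      "p_disc_nonstable": {
        "value": 0.214,
        "low": 0.1926,
        "high": 0.2354,
        "distribution_family": "beta"
      },
      "p_disc_stable": {
        "value": 0.0483,
        "low": 0.0435,
        "high": 0.0531,
        "distribution_family": "beta"
      },
      "p_relapse_stable": {
        "value": 0.0292,
        "low": 0.0263,
        "high": 0.0321,
        "distribution_family": "beta"
      },
      "p_relapse_nonadherent": {
        "value": 0.4731,
        "low": 0.4258,
        "high": 0.5204,
        "distribution_family": "beta"
      },
      "p_hosp_nonstable": {
        "value": 0.0102,
        "low": 0.0091,
        "high": 0.0112,
        "distribution_family": "beta"
      },
      "drug_cost_cycle_stable": {
        "mean": 958.87,
        "low": 767.1,
        "high": 1150.65,
        "distribution_family": "gamma",
        "basis": "per_cycle",
        "shared_id": "cost.drug_PP1M"
      },
      "drug_cost_cycle_nonstable": {
        "mean": 958.87,
        "low": 767.1,
        "high": 1150.65,
        "distribution_family": "gamma",
        "basis": "per_cycle",
        "shared_id": "cost.drug_PP1M"
      }
    },
    "PP3M": {
      "p_disc_nonstable": {
        "value": 0.214,
        "low": 0.1926,
        "high": 0.2354,
        "distribution_family": "beta"
      },
      "p_disc_stable": {
        "value": 0.0434,
        "low": 0.0391,
        "high": 0.0477,
        "distribution_family": "beta"
      },
      "p_relapse_stable": {
        "value": 0.024,
        "low": 0.0216,
        "high": 0.0264,
        "distribution_family": "beta"
      },
      "p_relapse_nonadherent": {
        "value": 0.3465,
        "low": 0.3119,
        "high": 0.3812,
        "distribution_family": "beta"
      },
      "p_hosp_nonstable": {
        "value": 0.0076,
        "low": 0.0071,
        "high": 0.0083,
        "distribution_family": "beta"
      },
      "drug_cost_cycle_stable": {
        "mean": 813.64,
        "low": 650.91,
        "high": 976.36,
        "distribution_family": "gamma",
        "basis": "per_cycle",
        "shared_id": "cost.drug_PP3M"
      },
      "drug_cost_cycle_nonstable": {
        "mean": 958.87,
        "low": 767.1,
        "high": 1150.65,
        "distribution_family": "gamma",
        "basis": "per_cycle",
        "shared_id": "cost.drug_PP1M"
      }
    },
    "ER": {
      "p_disc_nonstable": {
        "value": 0.2831,
        "low": 0.2548,
        "high": 0.3114,
        "distribution_family": "beta"
      },
      "p_disc_stable": {
        "value": 0.1792,
        "low": 0.1613,
        "high": 0.1971,
        "distribution_family": "beta"
      },
      "p_relapse_stable": {
        "value": 0.2655,
        "low": 0.239,
        "high": 0.2921,
        "distribution_family": "beta"
      },
      "p_relapse_nonadherent": {
        "value": 0.9864,
        "low": 0.8878,
        "high": 1,
        "distribution_family": "beta"
      },
      "p_hosp_nonstable": {
        "value": 0.0503,
        "low": 0.0453,
        "high": 0.0554,
        "distribution_family": "beta"
      },
      "drug_cost_cycle_stable": {
        "mean": 759.09,
        "low": 607.27,
        "high": 910.91,
        "distribution_family": "gamma",
        "basis": "per_cycle",
        "shared_id": "cost.drug_ER"
      },
      "drug_cost_cycle_nonstable": {
        "mean": 759.09,
        "low": 607.27,
        "high": 910.91,
        "distribution_family": "gamma",
        "basis": "per_cycle",
        "shared_id": "cost.drug_ER"
      }
    }
  },
  "config": {
    "horizon_years": 20,
    "cycle_months": 3,
    "annual_discount_rate": 0.05,
    "discount_low": 0,
    "discount_high": 0.08,
    "start_age": 38,
    "wtp_per_qaly": 12756.55,
    "utilities": {
      "stable": {
        "per_cycle_weight": 0.23,
        "low": 0.21,
        "high": 0.25,
        "distribution_family": "beta"
      },
      "non_stable": {
        "per_cycle_weight": 0.15,
        "low": 0.14,
        "high": 0.17,
        "distribution_family": "beta"
      },
      "relapse": {
        "per_cycle_weight": 0.15,
        "low": 0.14,
        "high": 0.17,
        "distribution_family": "beta"
      }
    },
    "shared_costs": {
      "hospitalization": {
        "mean": 1998.9,
        "low": 1599.12,
        "high": 2398.68,
        "distribution_family": "gamma",
        "basis": "per_admission"
      },
      "outpatient_stable": {
        "mean": 127.52,
        "low": 102.02,
        "high": 153.03,
        "distribution_family": "gamma",
        "basis": "per_cycle"
      },
      "outpatient_nonstable": {
        "mean": 183.3,
        "low": 164.97,
        "high": 219.96,
        "distribution_family": "gamma",
        "basis": "per_cycle"
      }
    },
    "mortality": {
      "bands": [
        {
          "age_low": 35,
          "age_high": 39,
          "annual_probability": 0.006267
        },
        {
          "age_low": 40,
          "age_high": 44,
          "annual_probability": 0.004904
        },
        {
          "age_low": 45,
          "age_high": 49,
          "annual_probability": 0.007708
        },
        {
          "age_low": 50,
          "age_high": 54,
          "annual_probability": 0.007606
        },
        {
          "age_low": 55,
          "age_high": 59,
          "annual_probability": 0.011745
        },
        {
          "age_low": 60,
          "age_high": 64,
          "annual_probability": 0.03561
        },
        {
          "age_low": 65,
          "age_high": 78,
          "annual_probability": 0.016676
        }
      ]
    },
    "relapse_hospitalization_policy": "never"
  }
}
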