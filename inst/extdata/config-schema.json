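{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ceindex assessment configuration",
  "type": "object",
  "required": ["assessment", "sites", "services"],
  "properties": {
    "assessment": {
      "type": "object",
      "required": ["evaluation_year"],
      "properties": {
        "evaluation_year": {"type": "integer"},
        "window_years": {"type": "integer", "minimum": 2, "default": 5},
        "beta": {"type": "number", "minimum": 0, "maximum": 1, "default": 0.67},
        "outlier_k": {"type": "number", "exclusiveMinimum": 0, "default": 2},
        "report_scale": {"enum": ["percent100", "unit"], "default": "percent100"},
        "min_trend_points": {"type": "integer", "minimum": 1, "default": 3},
        "pr_years": {"enum": ["evaluation", "window"], "default": "evaluation"}
      }
    },
    "sites": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["site_id"],
        "properties": {
          "site_id": {"type": "string"},
          "name": {"type": "string"},
          "natural_or_artificial": {"enum": ["natural", "artificial"]},
          "area_m2": {"type": "number", "exclusiveMinimum": 0},
          "coastline_m": {"type": "number", "exclusiveMinimum": 0}
        }
      }
    },
    "services": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["service_id"],
        "properties": {
          "service_id": {"type": "string"},
          "name": {"type": "string"},
          "index_description": {"type": "string"},
          "spatial_basis": {"enum": ["per_unit_area", "whole_site"],
                            "default": "per_unit_area"},
          "temporal_statistic": {"enum": ["annual_mean", "annual_total",
                                          "annual_max", "annual_min"],
                                 "default": "annual_mean"},
          "unit": {"type": "string"}
        }
      }
    },
    "factors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["factor_id", "service_id", "kind"],
        "properties": {
          "factor_id": {"type": "string"},
          "service_id": {"type": "string",
                         "description": "must reference a declared service"},
          "kind": {"enum": ["quantitative", "qualitative"]},
          "lo_threshold": {"type": "number",
                           "description": "quantitative only; score saturates at -1"},
          "hi_threshold": {"type": "number",
                           "description": "quantitative only; score saturates at +1; must exceed lo_threshold"},
          "direction": {"enum": ["increasing_good", "decreasing_good"],
                        "default": "increasing_good"},
          "qualitative_magnitude": {"type": "number", "exclusiveMinimum": 0,
                                    "maximum": 1, "default": 0.5},
          "weight": {"type": "number", "exclusiveMinimum": 0, "default": 1},
          "description": {"type": "string"}
        }
      }
    },
    "reference_points": {
      "type": "object",
      "description": "optional fixed normalization ceilings, service_id -> positive number",
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    }
  }
}
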