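{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "isletscope acquisition manifest",
  "description": "Index of a tiled, burst-captured fluorescence time-lapse acquisition. 12-bit pixel data are stored in 16-bit grayscale TIFF containers; the declared bit_depth bounds every pixel value.",
  "type": "object",
  "required": ["pixel_size_um", "bit_depth", "time_points", "tile_grid",
               "tile_shape_px", "overlap_fraction", "burst_size",
               "frame_index"],
  "properties": {
    "format": {"const": "isletscope-acquisition"},
    "pixel_size_um": {"type": "number", "exclusiveMinimum": 0},
    "bit_depth": {"type": "integer", "minimum": 8, "maximum": 16},
    "time_points": {
      "type": "array", "items": {"type": "number"},
      "description": "acquisition times in minutes, ascending"
    },
    "cadence_min": {"type": "number", "exclusiveMinimum": 0},
    "tile_grid": {
      "type": "array", "items": {"type": "integer", "minimum": 1},
      "minItems": 2, "maxItems": 2,
      "description": "rows, cols of the stage tiling"
    },
    "tile_shape_px": {
      "type": "array", "items": {"type": "integer", "minimum": 32},
      "minItems": 2, "maxItems": 2,
      "description": "height, width of one field in pixels"
    },
    "overlap_fraction": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
    "burst_size": {"type": "integer", "minimum": 1},
    "phase_schedule": {
      "type": "object",
      "properties": {
        "phase": {"type": "array", "items": {"type": "string"}},
        "duration_min": {"type": "array", "items": {"type": "number"}},
        "release_fraction": {"type": "array", "items": {"type": "number"}}
      }
    },
    "frame_index": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["time_point", "tile", "burst", "file", "page"],
        "properties": {
          "time_point": {"type": "number"},
          "tile": {"type": "integer", "minimum": 0,
                   "description": "0-based, row-major"},
          "burst": {"type": "integer", "minimum": 0},
          "file": {"type": "string",
                   "description": "TIFF path relative to the manifest"},
          "page": {"type": "integer", "minimum": 1}
        }
      }
    }
  }
}
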