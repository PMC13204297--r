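unit,sex,apc_mean,apc_lo,apc_hi,prob_target,prob_lo,prob_hi,target_year,on_track
Nationwide,total,0.83,-0.05,1.67,0.113,0.063,0.163,2040,FALSE
Nationwide,men,0.64,-0.35,1.55,0.254,0.204,0.304,2040,FALSE
Nationwide,women,1.01,0.11,1.93,0.070,0.020,0.120,2039,FALSE
Hokkaido,total,0.55,-0.42,1.46,0.016,NA,NA,2080,FALSE
Hokkaido,men,0.52,-0.65,1.63,0.050,NA,NA,2075,FALSE
Hokkaido,women,0.56,-0.39,1.48,0.012,NA,NA,2086,FALSE
Aomori,total,1.23,-0.42,2.76,0.802,NA,NA,2028,TRUE
Aomori,men,0.96,-0.96,2.84,0.790,NA,NA,2029,TRUE
Aomori,women,1.34,0.17,2.36,0.794,NA,NA,2029,TRUE
Iwate,total,0.71,-0.22,1.60,0.877,NA,NA,2026,TRUE
Iwate,men,0.64,-1.34,2.69,0.782,NA,NA,2032,FALSE
Iwate,women,0.78,0.01,1.57,0.840,NA,NA,2028,TRUE
Miyagi,total,0.59,-0.81,2.01,0.846,NA,NA,2024,TRUE
Miyagi,men,0.32,-0.91,1.60,0.888,NA,NA,2015,TRUE
Miyagi,women,0.70,-1.13,2.45,0.707,NA,NA,2036,FALSE
Akita,total,0.57,-0.75,1.89,0.521,NA,NA,2042,FALSE
Akita,men,0.55,-0.87,1.93,0.744,NA,NA,2033,FALSE
Akita,women,0.75,-0.64,2.15,0.455,NA,NA,2039,FALSE
Yamagata,total,0.99,0.09,1.88,0.991,NA,NA,2014,TRUE
Yamagata,men,0.82,-0.37,2.08,0.981,NA,NA,2013,TRUE
Yamagata,women,1.18,-0.05,2.47,0.981,NA,NA,2016,TRUE
Fukushima,total,0.64,-0.38,1.66,0.564,NA,NA,2034,FALSE
Fukushima,men,0.45,-0.19,1.07,0.843,NA,NA,2027,TRUE
Fukushima,women,0.76,-0.79,2.22,0.346,NA,NA,2044,FALSE
Ibaraki,total,0.64,-1.24,2.53,0.267,NA,NA,2091,FALSE
Ibaraki,men,0.48,-1.54,2.50,0.365,NA,NA,never,FALSE
Ibaraki,women,0.77,-1.20,2.54,0.197,NA,NA,2063,FALSE
Tochigi,total,0.55,-0.86,1.98,0.273,NA,NA,2064,FALSE
Tochigi,men,0.37,-0.96,1.68,0.346,NA,NA,never,FALSE
Tochigi,women,0.66,-0.74,1.98,0.178,NA,NA,2053,FALSE
Gunma,total,0.84,-0.92,2.54,0.694,NA,NA,2033,FALSE
Gunma,men,0.70,-1.12,2.60,0.728,NA,NA,2037,FALSE
Gunma,women,0.95,-0.93,2.63,0.595,NA,NA,2035,FALSE
Saitama,total,0.68,-0.66,1.95,0.071,NA,NA,2060,FALSE
Saitama,men,0.33,-1.00,1.55,0.069,NA,NA,never,FALSE
Saitama,women,1.02,-0.23,2.13,0.071,NA,NA,2044,FALSE
Chiba,total,0.75,-0.24,1.76,0.214,NA,NA,2039,FALSE
Chiba,men,0.58,-0.26,1.39,0.292,NA,NA,2038,FALSE
Chiba,women,0.92,-0.11,1.95,0.170,NA,NA,2038,FALSE
Tokyo,total,1.16,-0.02,2.28,0.377,NA,NA,2034,FALSE
Tokyo,men,0.78,-0.49,1.93,0.381,NA,NA,2037,FALSE
Tokyo,women,1.48,0.21,2.56,0.407,NA,NA,2032,FALSE
Kanagawa,total,0.87,0.14,1.54,0.072,NA,NA,2037,FALSE
Kanagawa,men,0.56,-0.29,1.33,0.235,NA,NA,2039,FALSE
Kanagawa,women,1.16,0.49,1.79,0.039,NA,NA,2036,FALSE
Niigata,total,0.62,-0.86,2.12,0.850,NA,NA,2024,TRUE
Niigata,men,0.43,-1.20,2.20,0.852,NA,NA,2016,TRUE
Niigata,women,0.77,-0.44,1.92,0.810,NA,NA,2028,TRUE
Toyama,total,0.80,0.12,1.49,0.903,NA,NA,2026,TRUE
Toyama,men,0.51,-0.32,1.38,0.880,NA,NA,2025,TRUE
Toyama,women,1.03,0.22,1.82,0.879,NA,NA,2027,TRUE
Ishikawa,total,0.81,-0.64,2.18,0.597,NA,NA,2035,FALSE
Ishikawa,men,0.71,-1.41,2.81,0.737,NA,NA,2038,FALSE
Ishikawa,women,0.88,-0.22,1.87,0.240,NA,NA,2037,FALSE
Fukui,total,0.43,-0.24,1.08,0.041,NA,NA,2055,FALSE
Fukui,men,0.24,-0.48,0.96,0.075,NA,NA,never,FALSE
Fukui,women,0.73,0.07,1.43,0.051,NA,NA,2041,FALSE
Yamanashi,total,0.94,0.20,1.70,0.980,NA,NA,2019,TRUE
Yamanashi,men,0.67,-0.34,1.76,0.959,NA,NA,2017,TRUE
Yamanashi,women,1.15,0.27,2.06,0.970,NA,NA,2022,TRUE
Nagano,total,0.72,-0.08,1.50,0.737,NA,NA,2030,TRUE
Nagano,men,0.66,-0.38,1.73,0.885,NA,NA,2024,TRUE
Nagano,women,0.82,-0.06,1.66,0.345,NA,NA,2034,FALSE
Gifu,total,1.24,0.07,2.30,0.593,NA,NA,2031,FALSE
Gifu,men,1.33,0.07,2.56,0.916,NA,NA,2025,TRUE
Gifu,women,1.22,0.25,2.14,0.143,NA,NA,2035,FALSE
Shizuoka,total,0.61,-0.37,1.57,0.272,NA,NA,2040,FALSE
Shizuoka,men,0.48,-0.40,1.42,0.502,NA,NA,2038,FALSE
Shizuoka,women,0.71,-0.46,1.85,0.168,NA,NA,2045,FALSE
Aichi,total,0.84,-0.18,1.78,0.094,NA,NA,2042,FALSE
Aichi,men,0.63,-0.11,1.37,0.110,NA,NA,2041,FALSE
Aichi,women,1.04,-0.23,2.16,0.090,NA,NA,2042,FALSE
Mie,total,0.91,-0.35,2.10,0.167,NA,NA,2041,FALSE
Mie,men,0.67,-0.33,1.61,0.195,NA,NA,2041,FALSE
Mie,women,1.08,-0.49,2.43,0.150,NA,NA,2042,FALSE
Shiga,total,0.87,-0.72,2.32,0.184,NA,NA,2048,FALSE
Shiga,men,0.64,-1.13,2.33,0.377,NA,NA,2058,FALSE
Shiga,women,1.12,-0.29,2.33,0.111,NA,NA,2042,FALSE
Kyoto,total,0.49,-0.80,1.72,0.032,NA,NA,never,FALSE
Kyoto,men,0.33,-1.60,2.17,0.095,NA,NA,never,FALSE
Kyoto,women,0.60,-0.37,1.42,0.011,NA,NA,2073,FALSE
Osaka,total,1.10,-0.01,2.10,0.057,NA,NA,2042,FALSE
Osaka,men,1.03,-0.01,1.96,0.091,NA,NA,2039,FALSE
Osaka,women,1.12,-0.19,2.13,0.045,NA,NA,2044,FALSE
Hyogo,total,0.82,-0.24,1.90,0.049,NA,NA,2050,FALSE
Hyogo,men,0.42,-1.25,1.97,0.104,NA,NA,never,FALSE
Hyogo,women,1.11,0.41,1.80,0.021,NA,NA,2040,FALSE
Nara,total,1.00,-0.42,2.22,0.090,NA,NA,2045,FALSE
Nara,men,1.06,0.12,2.00,0.367,NA,NA,2033,FALSE
Nara,women,0.90,-0.82,2.25,0.054,NA,NA,2058,FALSE
Wakayama,total,0.64,-0.28,1.46,0.028,NA,NA,2055,FALSE
Wakayama,men,0.46,-0.22,1.10,0.022,NA,NA,2062,FALSE
Wakayama,women,0.84,-0.04,1.63,0.024,NA,NA,2048,FALSE
Tottori,total,0.86,0.07,1.70,0.799,NA,NA,2029,TRUE
Tottori,men,0.76,-0.83,2.30,0.806,NA,NA,2028,TRUE
Tottori,women,0.99,0.18,1.78,0.688,NA,NA,2030,TRUE
Shimane,total,0.91,-0.69,2.50,0.719,NA,NA,2032,FALSE
Shimane,men,0.68,-1.69,2.97,0.688,NA,NA,2062,FALSE
Shimane,women,1.09,-0.26,2.32,0.678,NA,NA,2031,FALSE
Okayama,total,0.63,0.00,1.26,0.696,NA,NA,2030,TRUE
Okayama,men,0.59,-0.02,1.28,0.874,NA,NA,2027,TRUE
Okayama,women,0.70,0.04,1.34,0.481,NA,NA,2032,FALSE
Hiroshima,total,0.75,0.03,1.42,0.027,NA,NA,2045,FALSE
Hiroshima,men,0.91,-0.02,1.84,0.368,NA,NA,2034,FALSE
Hiroshima,women,0.54,-0.22,1.23,0.009,NA,NA,2071,FALSE
Yamaguchi,total,0.48,-0.13,1.12,0.011,NA,NA,2068,FALSE
Yamaguchi,men,0.44,-0.33,1.18,0.048,NA,NA,2058,FALSE
Yamaguchi,women,0.41,-0.27,1.06,0.005,NA,NA,never,FALSE
Tokushima,total,0.82,-0.13,1.66,0.043,NA,NA,2045,FALSE
Tokushima,men,0.89,-0.56,2.23,0.219,NA,NA,2043,FALSE
Tokushima,women,0.83,0.02,1.57,0.020,NA,NA,2047,FALSE
Kagawa,total,0.76,-1.66,3.04,0.543,NA,NA,2064,FALSE
Kagawa,men,0.56,-1.76,3.09,0.610,NA,NA,never,FALSE
Kagawa,women,0.83,-1.45,2.91,0.393,NA,NA,2058,FALSE
Ehime,total,0.58,-0.14,1.28,0.028,NA,NA,2051,FALSE
Ehime,men,0.71,-0.70,2.04,0.383,NA,NA,2042,FALSE
Ehime,women,0.46,-0.53,1.38,0.018,NA,NA,2089,FALSE
Kochi,total,1.09,-0.13,2.24,0.841,NA,NA,2028,TRUE
Kochi,men,1.13,-0.01,2.21,0.916,NA,NA,2025,TRUE
Kochi,women,1.19,-0.28,2.57,0.811,NA,NA,2028,TRUE
Fukuoka,total,0.89,-0.32,1.96,0.060,NA,NA,2047,FALSE
Fukuoka,men,0.79,-0.37,1.85,0.115,NA,NA,2044,FALSE
Fukuoka,women,0.95,-0.24,1.98,0.040,NA,NA,2049,FALSE
Saga,total,1.01,0.40,1.62,0.490,NA,NA,2031,FALSE
Saga,men,0.96,-0.45,2.43,0.709,NA,NA,2031,FALSE
Saga,women,0.88,0.18,1.57,0.087,NA,NA,2036,FALSE
Nagasaki,total,0.83,0.29,1.36,0.013,NA,NA,2044,FALSE
Nagasaki,men,0.48,-0.09,1.04,0.011,NA,NA,2062,FALSE
Nagasaki,women,1.10,0.16,1.92,0.042,NA,NA,2041,FALSE
Kumamoto,total,0.67,-2.67,3.69,0.386,NA,NA,never,FALSE
Kumamoto,men,0.62,-2.97,3.95,0.529,NA,NA,never,FALSE
Kumamoto,women,0.70,-1.57,2.63,0.169,NA,NA,never,FALSE
Oita,total,0.85,-1.21,2.74,0.343,NA,NA,2054,FALSE
Oita,men,0.67,-1.41,2.71,0.483,NA,NA,2069,FALSE
Oita,women,1.04,-0.88,2.79,0.301,NA,NA,2044,FALSE
Miyazaki,total,0.88,-0.28,1.99,0.203,NA,NA,2039,FALSE
Miyazaki,men,0.91,-0.01,1.75,0.595,NA,NA,2031,FALSE
Miyazaki,women,0.97,-0.19,2.06,0.132,NA,NA,2040,FALSE
Kagoshima,total,0.50,-1.67,2.69,0.319,NA,NA,never,FALSE
Kagoshima,men,0.49,-1.53,2.54,0.436,NA,NA,never,FALSE
Kagoshima,women,0.47,-2.29,3.08,0.265,NA,NA,never,FALSE
Okinawa,total,0.36,-0.41,1.10,0.011,NA,NA,never,FALSE
Okinawa,men,0.21,-0.70,1.07,0.014,NA,NA,never,FALSE
Okinawa,women,0.54,-0.10,1.18,0.010,NA,NA,2064,FALSE
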