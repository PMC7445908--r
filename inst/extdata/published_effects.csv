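dimension,label,effect
age,20-24,-2.995
age,25-29,-1.822
age,30-34,-0.792
age,35-39,-0.350
age,40-44,0.034
age,45-49,0.394
age,50-54,0.525
age,55-59,0.643
age,60-64,0.692
age,65-69,0.764
age,70-74,0.843
age,75-79,0.968
age,80-84,1.096
period,1990,-0.141
period,1995,-0.114
period,2000,-0.073
period,2005,-0.020
period,2010,0.090
period,2015,0.258
cohort,1906-1910,0.626
cohort,1911-1915,0.577
cohort,1916-1920,0.565
cohort,1921-1925,0.554
cohort,1926-1930,0.550
cohort,1931-1935,0.518
cohort,1936-1940,0.487
cohort,1941-1945,0.414
cohort,1946-1950,0.407
cohort,1951-1955,0.306
cohort,1956-1960,0.099
cohort,1961-1965,-0.028
cohort,1966-1970,-0.223
cohort,1971-1975,-0.514
cohort,1976-1980,-0.726
cohort,1981-1985,-0.841
cohort,1986-1990,-1.020
cohort,1991-1995,-1.752
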