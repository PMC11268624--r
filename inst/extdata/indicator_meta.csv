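indicator,theme,direction,label
311,Maternal and reproductive health,lower_is_better,Maternal mortality rate (per 100000 live births)
312,Maternal and reproductive health,higher_is_better,Births assisted by qualified health personnel (%)
223,Maternal and reproductive health,lower_is_better,Pregnant women aged 15-49 with anaemia (%)
371,Maternal and reproductive health,higher_is_better,Family planning need satisfied with modern methods (%)
372,Maternal and reproductive health,lower_is_better,Adolescent birth rate (per 1000 women 15-19)
221,Infant and neonatal health,lower_is_better,Children under 5 with stunting (%)
222a,Infant and neonatal health,lower_is_better,Children under 5 with wasting (%)
222b,Infant and neonatal health,lower_is_better,Children under 5 with overweight (%)
321,Infant and neonatal health,lower_is_better,Under-5 mortality rate (per 1000 live births)
322,Infant and neonatal health,lower_is_better,Neonatal mortality rate (per 1000 live births)
3b1a,Infant and neonatal health,higher_is_better,DTP3 immunization coverage within 1 year (%)
3b1b,Infant and neonatal health,higher_is_better,MCV2 measles vaccination coverage (%)
3b1c,Infant and neonatal health,higher_is_better,PCV3 pneumococcal immunization coverage under 1 year (%)
331,Infectious diseases,lower_is_better,New HIV infections (per 1000 uninfected inhabitants)
332,Infectious diseases,lower_is_better,TB incidence (per 100000 inhabitants per year)
333,Infectious diseases,lower_is_better,Malaria incidence (per 1000 inhabitants at risk)
334,Infectious diseases,lower_is_better,HBsAg prevalence in children under 5 (%)
335,Infectious diseases,lower_is_better,Persons requiring interventions against neglected tropical diseases
211,Non-communicable diseases,lower_is_better,Prevalence of undernourishment (%)
341,Non-communicable diseases,lower_is_better,Probability of dying 30-70 from cardiovascular disease cancer diabetes or chronic respiratory disease (%)
342,Non-communicable diseases,lower_is_better,Crude suicide rate (per 100000 inhabitants)
352,Non-communicable diseases,lower_is_better,Total per capita alcohol consumption (15+ years)
3a1,Non-communicable diseases,lower_is_better,Age-standardized prevalence of current smoking (15+ years)
361,Violence and injuries,lower_is_better,Death rate due to road traffic injuries (per 100000 inhabitants)
1311,Violence and injuries,lower_is_better,Death rate from natural disasters (per 100000 inhabitants)
1611,Violence and injuries,lower_is_better,Homicide rate (per 100000 inhabitants)
1623,Violence and injuries,lower_is_better,Population 18-29 who experienced sexual violence by age 18 (%)
391,Environmental risks,lower_is_better,Mortality rate attributable to air and household pollution (per 100000)
392,Environmental risks,lower_is_better,Mortality rate attributed to unsafe WASH services (per 100000)
393,Environmental risks,lower_is_better,Mortality rate attributed to unintentional poisoning (per 100000)
611,Environmental risks,higher_is_better,Population using safely managed drinking water services (%)
621a,Environmental risks,higher_is_better,Population using safely managed sanitation services (%)
621b,Environmental risks,lower_is_better,Population practicing open defecation (%)
712,Environmental risks,higher_is_better,Population using clean fuels and technologies (%)
1162,Environmental risks,lower_is_better,Fine particulate matter (PM2.5)
1a2,Health systems and coverage,higher_is_better,Current health expenditure as percentage of GDP (%)
381,Health systems and coverage,higher_is_better,Coverage of essential health services
382,Health systems and coverage,lower_is_better,Population with large household expenditures on health (>10% of income) (%)
3c1a,Health systems and coverage,higher_is_better,Physicians (per 10000 inhabitants)
3c1b,Health systems and coverage,higher_is_better,Nursing and obstetric personnel (per 10000 inhabitants)
3c1c,Health systems and coverage,higher_is_better,Dentists (per 10000 inhabitants)
3c1d,Health systems and coverage,higher_is_better,Pharmacists (per 10000 inhabitants)
3d1,Health systems and coverage,higher_is_better,IHR capacity and health emergency preparedness (SPAR)
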