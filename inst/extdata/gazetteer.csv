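term,country
us,US
usa,US
u.s.a,US
united states,US
united states of america,US
america,US
new york,US
nyc,US
california,US
los angeles,US
san francisco,US
texas,US
houston,US
chicago,US
illinois,US
florida,US
miami,US
washington,US
seattle,US
boston,US
atlanta,US
georgia,US
philadelphia,US
phoenix,US
denver,US
uk,UK
u.k,UK
united kingdom,UK
great britain,UK
britain,UK
england,UK
scotland,UK
wales,UK
northern ireland,UK
london,UK
manchester,UK
birmingham,UK
liverpool,UK
leeds,UK
glasgow,UK
edinburgh,UK
bristol,UK
india,India
mumbai,India
delhi,India
new delhi,India
bangalore,India
bengaluru,India
chennai,India
kolkata,India
hyderabad,India
pune,India
maharashtra,India
canada,Canada
toronto,Canada
ontario,Canada
vancouver,Canada
british columbia,Canada
montreal,Canada
quebec,Canada
ottawa,Canada
calgary,Canada
alberta,Canada
edmonton,Canada
winnipeg,Canada
australia,Australia
sydney,Australia
melbourne,Australia
brisbane,Australia
perth,Australia
adelaide,Australia
queensland,Australia
victoria,Australia
new south wales,Australia
nigeria,Nigeria
lagos,Nigeria
abuja,Nigeria
kano,Nigeria
ibadan,Nigeria
port harcourt,Nigeria
ireland,Ireland
dublin,Ireland
cork,Ireland
galway,Ireland
limerick,Ireland
south africa,South Africa
johannesburg,South Africa
cape town,South Africa
durban,South Africa
pretoria,South Africa
gauteng,South Africa
france,France
paris,France
lyon,France
marseille,France
toulouse,France
bordeaux,France
japan,Japan
tokyo,Japan
osaka,Japan
kyoto,Japan
yokohama,Japan
south korea,South Korea
korea,South Korea
seoul,South Korea
busan,South Korea
singapore,Singapore
spain,Spain
madrid,Spain
barcelona,Spain
valencia,Spain
seville,Spain
germany,Germany
berlin,Germany
munich,Germany
hamburg,Germany
frankfurt,Germany
netherlands,Netherlands
amsterdam,Netherlands
rotterdam,Netherlands
the hague,Netherlands
utrecht,Netherlands
georgia,Georgia
tbilisi,Georgia
batumi,Georgia
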