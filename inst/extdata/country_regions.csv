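country,region
United Kingdom,UK & Ireland
UK,UK & Ireland
Scotland,UK & Ireland
England,UK & Ireland
Wales,UK & Ireland
Northern Ireland,UK & Ireland
Ireland,UK & Ireland
France,Western Europe
Belgium,Western Europe
Netherlands,Western Europe
Spain,Western Europe
Portugal,Western Europe
Italy,Western Europe
Switzerland,Western Europe
Germany,Central Europe
Czechia,Central Europe
Czech Republic,Central Europe
Poland,Central Europe
Austria,Central Europe
Slovakia,Central Europe
Hungary,Central Europe
Russia,Eastern Europe
Ukraine,Eastern Europe
Belarus,Eastern Europe
Estonia,Eastern Europe
Latvia,Eastern Europe
Lithuania,Eastern Europe
USA,North America
United States,North America
Canada,North America
Mexico,North America
Greenland,North America
South Africa,Africa
Namibia,Africa
Zimbabwe,Africa
Morocco,Africa
Algeria,Africa
Egypt,Africa
Niger,Africa
China,Asia
Kazakhstan,Asia
Siberia,Asia
Mongolia,Asia
India,Asia
Iran,Asia
Turkey,Asia
Saudi Arabia,Asia
Vietnam,Asia
Brazil,South America
Uruguay,South America
Argentina,South America
Chile,South America
Bolivia,South America
Peru,South America
Paraguay,South America
Australia,Oceania
New Zealand,Oceania
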